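# Example deployment metadata: the two South Orkney AURAL moorings
# (Coronation Trough), duty-cycled 12/60 and 8/60 min at 32768 Hz.
aural_2016:
  start: "2016-02-16 00:00:00"
  end: "2016-08-23 23:59:59"
  duty_on: 12
  fs: 32768
  lat: -60.40495
  lon: -45.95913
  depth: 240
aural_2017:
  start: "2017-02-10 00:00:00"
  end: "2017-10-12 23:59:59"
  duty_on: 8
  fs: 32768
  lat: -60.40468
  lon: -45.97185
  depth: 286
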