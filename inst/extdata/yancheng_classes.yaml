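nodata: 0
classes:
  - {code: 1, name: phragmites, dynamic: true}
  - {code: 2, name: suaeda, dynamic: true}
  - {code: 3, name: spartina, dynamic: false}
  - {code: 4, name: mudflat, dynamic: true}
  - {code: 5, name: water, dynamic: false}
  - {code: 6, name: pond, dynamic: false}
  - {code: 7, name: road, dynamic: false}
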