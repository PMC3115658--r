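sound_speed: 3.0
channels:
- channel: 1
  x: -6.0
  'y': 0.0
  z: 26.0
  side: left
  quadrant: top-left
- channel: 2
  x: -11.0
  'y': 0.0
  z: 22.0
  side: left
  quadrant: top-left
- channel: 3
  x: -6.0
  'y': 0.0
  z: 18.0
  side: left
  quadrant: top-left
- channel: 4
  x: -11.0
  'y': 0.0
  z: 14.0
  side: left
  quadrant: top-left
- channel: 5
  x: -6.0
  'y': 0.0
  z: 10.0
  side: left
  quadrant: bottom-left
- channel: 6
  x: -11.0
  'y': 0.0
  z: 6.0
  side: left
  quadrant: bottom-left
- channel: 7
  x: -6.0
  'y': 0.0
  z: 2.0
  side: left
  quadrant: bottom-left
- channel: 8
  x: 6.0
  'y': 0.0
  z: 26.0
  side: right
  quadrant: top-right
- channel: 9
  x: 11.0
  'y': 0.0
  z: 22.0
  side: right
  quadrant: top-right
- channel: 10
  x: 6.0
  'y': 0.0
  z: 18.0
  side: right
  quadrant: top-right
- channel: 11
  x: 11.0
  'y': 0.0
  z: 14.0
  side: right
  quadrant: top-right
- channel: 12
  x: 6.0
  'y': 0.0
  z: 10.0
  side: right
  quadrant: bottom-right
- channel: 13
  x: 11.0
  'y': 0.0
  z: 6.0
  side: right
  quadrant: bottom-right
- channel: 14
  x: 6.0
  'y': 0.0
  z: 2.0
  side: right
  quadrant: bottom-right
- channel: 15
  x: -6.0
  'y': 20.0
  z: 16.0
  side: left
  quadrant: top-left
- channel: 16
  x: 6.0
  'y': 20.0
  z: 16.0
  side: right
  quadrant: top-right
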