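# Default clinical montage: 28 emitter-detector channels over the motor
# cortex (10-20/10-10 positions), 14 homotopic pairs. Emitters at
# F3/FC5/FC1/C3/CP5/CP1/P3 and their right homologues; detectors at
# FC3/C5/C1/CP3 and right homologues. The channel adjacency set is the
# package's default selection of 14 short (~3 cm) pairs per hemisphere.
name: clinical28
protocol: clinical
fs_default: 15.6
channels:
  - {id: F3-FC3,  emitter: F3,  detector: FC3, hemisphere: left}
  - {id: FC5-FC3, emitter: FC5, detector: FC3, hemisphere: left}
  - {id: FC5-C5,  emitter: FC5, detector: C5,  hemisphere: left}
  - {id: FC1-FC3, emitter: FC1, detector: FC3, hemisphere: left}
  - {id: FC1-C1,  emitter: FC1, detector: C1,  hemisphere: left}
  - {id: C3-FC3,  emitter: C3,  detector: FC3, hemisphere: left}
  - {id: C3-C5,   emitter: C3,  detector: C5,  hemisphere: left}
  - {id: C3-C1,   emitter: C3,  detector: C1,  hemisphere: left}
  - {id: C3-CP3,  emitter: C3,  detector: CP3, hemisphere: left}
  - {id: CP5-C5,  emitter: CP5, detector: C5,  hemisphere: left}
  - {id: CP5-CP3, emitter: CP5, detector: CP3, hemisphere: left}
  - {id: CP1-C1,  emitter: CP1, detector: C1,  hemisphere: left}
  - {id: CP1-CP3, emitter: CP1, detector: CP3, hemisphere: left}
  - {id: P3-CP3,  emitter: P3,  detector: CP3, hemisphere: left}
  - {id: F4-FC4,  emitter: F4,  detector: FC4, hemisphere: right}
  - {id: FC6-FC4, emitter: FC6, detector: FC4, hemisphere: right}
  - {id: FC6-C6,  emitter: FC6, detector: C6,  hemisphere: right}
  - {id: FC2-FC4, emitter: FC2, detector: FC4, hemisphere: right}
  - {id: FC2-C2,  emitter: FC2, detector: C2,  hemisphere: right}
  - {id: C4-FC4,  emitter: C4,  detector: FC4, hemisphere: right}
  - {id: C4-C6,   emitter: C4,  detector: C6,  hemisphere: right}
  - {id: C4-C2,   emitter: C4,  detector: C2,  hemisphere: right}
  - {id: C4-CP4,  emitter: C4,  detector: CP4, hemisphere: right}
  - {id: CP6-C6,  emitter: CP6, detector: C6,  hemisphere: right}
  - {id: CP6-CP4, emitter: CP6, detector: CP4, hemisphere: right}
  - {id: CP2-C2,  emitter: CP2, detector: C2,  hemisphere: right}
  - {id: CP2-CP4, emitter: CP2, detector: CP4, hemisphere: right}
  - {id: P4-CP4,  emitter: P4,  detector: CP4, hemisphere: right}
symmetric_pairs:
  - [F3-FC3,  F4-FC4]
  - [FC5-FC3, FC6-FC4]
  - [FC5-C5,  FC6-C6]
  - [FC1-FC3, FC2-FC4]
  - [FC1-C1,  FC2-C2]
  - [C3-FC3,  C4-FC4]
  - [C3-C5,   C4-C6]
  - [C3-C1,   C4-C2]
  - [C3-CP3,  C4-CP4]
  - [CP5-C5,  CP6-C6]
  - [CP5-CP3, CP6-CP4]
  - [CP1-C1,  CP2-C2]
  - [CP1-CP3, CP2-CP4]
  - [P3-CP3,  P4-CP4]
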