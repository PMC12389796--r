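# Default healthy-control montage: 33 channels over sensorimotor cortex
# (10-5 positions). Only the seven homotopic channel pairs covering the
# central sensorimotor strip - those whose exact positional mirror exists
# in the montage (with emitter/detector roles allowed to swap across the
# midline) - are declared symmetric and enter paired analyses; remaining
# channels are unpaired.
name: healthy33
protocol: healthy
fs_default: 3.9
channels:
  - {id: CCP1h-FCC1h, emitter: CCP1h, detector: FCC1h, hemisphere: left}
  - {id: CCP1h-CCP3h, emitter: CCP1h, detector: CCP3h, hemisphere: left}
  - {id: FCC3h-FCC1h, emitter: FCC3h, detector: FCC1h, hemisphere: left}
  - {id: FCC3h-FCC5h, emitter: FCC3h, detector: FCC5h, hemisphere: left}
  - {id: FCC3h-FFC3h, emitter: FCC3h, detector: FFC3h, hemisphere: left}
  - {id: CCP5h-CCP3h, emitter: CCP5h, detector: CCP3h, hemisphere: left}
  - {id: CCP5h-FCC5h, emitter: CCP5h, detector: FCC5h, hemisphere: left}
  - {id: FFC5h-FFC3h, emitter: FFC5h, detector: FFC3h, hemisphere: left}
  - {id: FFC5h-FCC5h, emitter: FFC5h, detector: FCC5h, hemisphere: left}
  - {id: FFC1h-FFC3h, emitter: FFC1h, detector: FFC3h, hemisphere: left}
  - {id: FFC1h-FCC1h, emitter: FFC1h, detector: FCC1h, hemisphere: left}
  - {id: CPP3h-CCP3h, emitter: CPP3h, detector: CCP3h, hemisphere: left}
  - {id: AFF1-FFC3h,  emitter: AFF1,  detector: FFC3h, hemisphere: left}
  - {id: FTT7h-FCC5h, emitter: FTT7h, detector: FCC5h, hemisphere: left}
  - {id: FCC2h-CCP2h, emitter: FCC2h, detector: CCP2h, hemisphere: right}
  - {id: CCP4h-CCP2h, emitter: CCP4h, detector: CCP2h, hemisphere: right}
  - {id: FCC2h-FCC4h, emitter: FCC2h, detector: FCC4h, hemisphere: right}
  - {id: FCC6h-FCC4h, emitter: FCC6h, detector: FCC4h, hemisphere: right}
  - {id: FFC4h-FCC4h, emitter: FFC4h, detector: FCC4h, hemisphere: right}
  - {id: CCP4h-CCP6h, emitter: CCP4h, detector: CCP6h, hemisphere: right}
  - {id: FCC6h-CCP6h, emitter: FCC6h, detector: CCP6h, hemisphere: right}
  - {id: FFC4h-FFC2h, emitter: FFC4h, detector: FFC2h, hemisphere: right}
  - {id: FCC2h-FFC2h, emitter: FCC2h, detector: FFC2h, hemisphere: right}
  - {id: AFF2-FFC2h,  emitter: AFF2,  detector: FFC2h, hemisphere: right}
  - {id: CPP6h-CCP6h, emitter: CPP6h, detector: CCP6h, hemisphere: right}
  - {id: CPP2h-CCP2h, emitter: CPP2h, detector: CCP2h, hemisphere: right}
  - {id: CPP4h-CCP6h, emitter: CPP4h, detector: CCP6h, hemisphere: right}
  - {id: CPP4h-CCP2h, emitter: CPP4h, detector: CCP2h, hemisphere: right}
  - {id: FFC5h-FCC3h, emitter: FFC5h, detector: FCC3h, hemisphere: left}
  - {id: CCP1h-CCP2h, emitter: CCP1h, detector: CCP2h, hemisphere: left}
  - {id: FCC2h-FCC1h, emitter: FCC2h, detector: FCC1h, hemisphere: right}
  - {id: FFC1h-FFC2h, emitter: FFC1h, detector: FFC2h, hemisphere: left}
  - {id: AFF1-FFC2h,  emitter: AFF1,  detector: FFC2h, hemisphere: left}
symmetric_pairs:
  - [CCP1h-FCC1h, FCC2h-CCP2h]
  - [CCP1h-CCP3h, CCP4h-CCP2h]
  - [FCC3h-FCC1h, FCC2h-FCC4h]
  - [FCC3h-FCC5h, FCC6h-FCC4h]
  - [FCC3h-FFC3h, FFC4h-FCC4h]
  - [CCP5h-CCP3h, CCP4h-CCP6h]
  - [CCP5h-FCC5h, FCC6h-CCP6h]
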