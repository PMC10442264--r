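second_order:
  KS01: KS
  KS02: KS
  KS03: KS
  KS04: KS
  KS05: KS
  KS06: KS
  KS07: KS
  KS08: KS
  KS09: KS
  KS10: KS
  PD01: PD
  PD02: PD
  PD03: PD
  PD04: PD
  PD05: PD
  RR01: RR
  RR02: RR
  RR03: RR
  RR04: RR
  RR05: RR
first_order_units:
  T3:
  - - KS01
    - KS02
    - KS03
  - - KS04
    - KS05
    - KS06
  - - KS07
    - KS08
  - - KS09
    - KS10
  - - PD01
    - PD02
    - PD03
  - - PD04
    - PD05
  - - RR01
    - RR02
    - RR03
  - - RR04
    - RR05
third_order_pairs:
  T3:
  - - KS
    - PD
  - - KS
    - RR
  - - PD
    - RR
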