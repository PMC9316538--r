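# Indicator specification for sterilized milk under GB 25190-2010
# (National Standard for Food Safety, Sterilized Milk). One record per
# laboratory test item; bound_kind gives the direction of the legal limit
# and standard_ref the analytical method standard.
indicators:
  - name: lactose
    unit: g/100 g
    bound_kind: max_limit
    hi: 2.0
    standard_ref: GB 5009.8-2016
  - name: acidity
    unit: "°T"
    bound_kind: interval
    lo: 11.0
    hi: 16.0
    standard_ref: GB 5413.34-2010
  - name: nms
    unit: g/100 g
    bound_kind: min_limit
    lo: 8.5
    standard_ref: GB 5413.39-2010
  - name: fat
    unit: g/100 g
    bound_kind: min_limit
    lo: 3.7
    standard_ref: GB 5413.3-2010
  - name: protein
    unit: g/100 g
    bound_kind: min_limit
    lo: 3.1
    standard_ref: GB 5009.5-2010
  - name: am1
    unit: "µg/kg"
    bound_kind: max_limit
    hi: 0.5
    standard_ref: GB 2761-2017
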