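# Example override config: undiscounted analysis with cheaper nilotinib.
# Any field omitted here keeps its packaged base-case value.
econ:
  discount_rate: 0.0
drugs:
  nilotinib:
    annual_cost: 15000
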