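# Editable establishment taxonomy: CNAE-style activity-code prefixes mapped
# to the 13 CAISAN subcategories. Codes are matched by longest prefix;
# unmatched codes count as non_food. Edit prefixes to match your registry's
# code formatting, and the swamp set to your chosen swamp definition.
subcategories:
  butchery:
    macro_class: in_natura
    code_prefixes: ["4722-9/01"]
  seafood:
    macro_class: in_natura
    code_prefixes: ["4722-9/02"]
  fruits_vegetables:
    macro_class: in_natura
    code_prefixes: ["4724-5"]
  street_vendor:
    macro_class: ultraprocessed
    code_prefixes: ["5612-1"]
  bar:
    macro_class: ultraprocessed
    code_prefixes: ["5611-2/02"]
  cafeteria:
    macro_class: ultraprocessed
    code_prefixes: ["5611-2/03"]
  convenience:
    macro_class: ultraprocessed
    code_prefixes: ["4729-6/02"]
  candy:
    macro_class: ultraprocessed
    code_prefixes: ["4721-1/04"]
  hypermarket_supermarket:
    macro_class: mixed
    code_prefixes: ["4711-3"]
  food_store:
    macro_class: mixed
    code_prefixes: ["4729-6/99"]
  mini_market:
    macro_class: mixed
    code_prefixes: ["4712-1"]
  bakery:
    macro_class: mixed
    code_prefixes: ["4721-1/02"]
  restaurant:
    macro_class: mixed
    code_prefixes: ["5611-2/01"]
swamp_subcategories: [convenience, cafeteria, mini_market, candy]
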