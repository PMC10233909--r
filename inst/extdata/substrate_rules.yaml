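# Default CAZyme-composition -> substrate rule table.
#
# Each rule fires when every required group is satisfied by at least one
# family in the locus (subfamilies such as GH5_2 match their parent
# family), the locus carries at least min_sulfatases sulfatase genes, and
# -- for exclusive rules -- no family outside the listed set is present.
# The shipped mappings are field-standard marker combinations for marine
# algal polysaccharides; edit or extend this file and load it with
# readSubstrateRules() to change the inference.
rules:
  - rule_id: beta_glucan_laminarin
    substrate: beta-glucan/laminarin
    required_groups:
      - [GH3]
      - [GH16]
    exclusive: false
    min_sulfatases: 0
  - rule_id: alpha_glucan
    substrate: alpha-glucan
    required_groups:
      - [GH13]
      - [GH65]
    exclusive: false
    min_sulfatases: 0
  - rule_id: alginate
    substrate: alginate
    required_groups:
      - [PL6, PL7, PL12, PL17]
    exclusive: false
    min_sulfatases: 0
  - rule_id: xylose_esterase
    substrate: xylose-containing
    required_groups:
      - [CE1, CE3, CE4]
    exclusive: true
    min_sulfatases: 0
  - rule_id: fcsp_fucoidan
    substrate: FCSP/fucoidan
    required_groups:
      - [GH29, GH106]
    exclusive: false
    min_sulfatases: 1
  - rule_id: ulvan
    substrate: ulvan
    required_groups:
      - [PL25, PL40]
    exclusive: false
    min_sulfatases: 0
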