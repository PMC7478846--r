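# Editable growth-medium presets: medium name -> {exchange id: maximum
# uptake rate, mmol/gDW/h}. The per-nutrient defaults are 10 for glucose
# and 1 for each amino acid and nucleobase; edit the exchange ids to match
# the loaded model (ids below follow the generic EX_<metabolite> scheme).
sdc:
  EX_glc: 10
  EX_ala: 1
  EX_arg: 1
  EX_asn: 1
  EX_asp: 1
  EX_cys: 1
  EX_gln: 1
  EX_glu: 1
  EX_gly: 1
  EX_his: 1
  EX_ile: 1
  EX_leu: 1
  EX_lys: 1
  EX_met: 1
  EX_phe: 1
  EX_pro: 1
  EX_ser: 1
  EX_thr: 1
  EX_trp: 1
  EX_tyr: 1
  EX_val: 1
  EX_ade: 1
  EX_ura: 1
ypd:
  EX_glc: 10
  EX_ala: 1
  EX_arg: 1
  EX_asn: 1
  EX_asp: 1
  EX_cys: 1
  EX_gln: 1
  EX_glu: 1
  EX_gly: 1
  EX_his: 1
  EX_ile: 1
  EX_leu: 1
  EX_lys: 1
  EX_met: 1
  EX_phe: 1
  EX_pro: 1
  EX_ser: 1
  EX_thr: 1
  EX_trp: 1
  EX_tyr: 1
  EX_val: 1
  EX_ade: 1
  EX_gua: 1
  EX_cyt: 1
  EX_ura: 1
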