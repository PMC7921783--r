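# Five-ingredient Wuhu San prescription: recipe percentages (total 99.8),
# official source species per ingredient, known market adulterants, and the
# positive-control species used in spiked mock samples.
ingredients:
  - pinyin: Danggui
    species: [Angelica sinensis]
    proportion: 21.3
  - pinyin: Honghua
    species: [Carthamus tinctorius]
    proportion: 21.3
  - pinyin: Fangfeng
    species: [Saposhnikovia divaricata]
    proportion: 21.3
  - pinyin: Zhitiannanxing
    species: [Arisaema amurense, Arisaema erubescens, Arisaema heterophyllum]
    proportion: 21.3
  - pinyin: Baizhi
    species: [Angelica dahurica]
    proportion: 14.6
adulterants:
  Ferula bungeana: Fangfeng
positive_control: Panax quinquefolius
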