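pt	site	reports_faers
Gastric ulcer	upper	26627
Duodenal ulcer perforation	upper	23916
Colitis ulcerative	lower	19013
Ulcer	not_classified	16492
Duodenal ulcer	upper	10697
Gastric ulcer hemorrhage	upper	9533
Gastritis erosive	upper	7694
Hemorrhagic ulcer	not_classified	5915
Hemorrhagic duodenal ulcer	upper	5216
Esophageal ulcer	upper	4839
Peptic ulcer	upper	4701
Large intestinal ulcer	lower	2624
Erosive esophagitis	upper	2523
Hemorrhagic gastritis	upper	2443
Gastrointestinal ulcer	not_classified	2184
Perforation of gastric ulcer	upper	1601
Rectal ulcer	lower	1542
Erosive duodenitis	upper	1289
Hemorrhagic gastrointestinal ulcer	not_classified	1230
Intestinal ulcer	not_classified	1210
Ulcerative esophagitis	upper	1134
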