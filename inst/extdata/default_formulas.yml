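# Default cofactor search formulas.
#
# Every entry is RECONSTRUCTED: an educated-guess formula keyed on cofactor
# ChEBI ids and EC-number presence, intended for catalogs whose chebi_id
# column carries the canonical cofactor ids. Override with any catalog/formula
# pair via read_formula_file().
#
# Syntax per leaf: field:"substring" | field~"regex" | field="EXACT-TAG",
# combined with AND / OR / NOT and parentheses. Fields: accession,
# entry_name, ec, catalytic, nucleotide, keyword, chebi.

all_enzymes:
  reconstructed: true
  enzymes: 'ec~"[0-9]" OR keyword="KW-0560" OR keyword="KW-0808" OR keyword="KW-0378" OR keyword="KW-0456" OR keyword="KW-0413" OR keyword="KW-0436"'

b_vitamin_enzymes:
  reconstructed: true
  enzymes: 'chebi="CHEBI:57540" OR chebi="CHEBI:58349" OR chebi="CHEBI:597326" OR chebi="CHEBI:57287" OR chebi="CHEBI:57692" OR chebi="CHEBI:58210" OR chebi="CHEBI:58937" OR chebi="CHEBI:57453" OR chebi="CHEBI:57586" OR chebi="CHEBI:18408"'

NIA:
  reconstructed: true
  enzymes: 'chebi="CHEBI:57540" OR chebi="CHEBI:58349"'
  metabolites: 'chebi="CHEBI:57540" OR chebi="CHEBI:58349"'

B6:
  reconstructed: true
  enzymes: 'chebi="CHEBI:597326"'
  metabolites: 'chebi="CHEBI:597326"'

PA:
  reconstructed: true
  enzymes: 'chebi="CHEBI:57287"'
  metabolites: 'chebi="CHEBI:57287"'

B2:
  reconstructed: true
  enzymes: 'chebi="CHEBI:57692" OR chebi="CHEBI:58210"'
  metabolites: 'chebi="CHEBI:57692" OR chebi="CHEBI:58210"'

B1:
  reconstructed: true
  enzymes: 'chebi="CHEBI:58937"'
  metabolites: 'chebi="CHEBI:58937"'

ATP:
  reconstructed: true
  enzymes: 'chebi="CHEBI:30616"'
  metabolites: 'chebi="CHEBI:30616"'

SAM:
  reconstructed: true
  enzymes: 'chebi="CHEBI:59789"'
  metabolites: 'chebi="CHEBI:59789"'

Gly:
  reconstructed: true
  enzymes: 'chebi="CHEBI:57305"'
  metabolites: 'chebi="CHEBI:57305"'

C1:
  reconstructed: true
  enzymes: 'chebi="CHEBI:15636" OR chebi="CHEBI:57453" OR chebi="CHEBI:59789" OR chebi="CHEBI:57305"'
  metabolites: 'chebi="CHEBI:15636" OR chebi="CHEBI:57453" OR chebi="CHEBI:59789" OR chebi="CHEBI:57305"'
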