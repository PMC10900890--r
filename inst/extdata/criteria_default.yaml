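# Default producer-phenotype criteria: thresholds on weighted pathway
# completeness (best corrin-ring branch + nucleotide loop, weighted by family
# counts). These defaults are a documented reconstruction; edit to taste.
very_likely_min: 0.8
likely_min: 0.6
possible_min: 0.4
require_loop: false
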