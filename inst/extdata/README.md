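# Bundled count tables

Published summary counts for NBS-encoding genes in the tomato, potato and
pepper genomes, used as worked-example inputs for the package's arithmetic
(ratios, proportions, and the duplication-loss ledger). All files are
tab-separated with a header row.

- `solanaceae_classification_counts.tsv` — genes per species, subclass
  (TNL/CNL/RNL) and architecture category (intact/TN/NL/N).
- `solanaceae_organization_counts.tsv` — per-species locus/gene counts from
  the 250-kb cluster rule.
- `solanaceae_duplication_counts.tsv` — new duplicated genes per species and
  duplication mechanism.
- `solanaceae_branch_events.tsv` — per-species-tree-branch gene gains and
  losses inferred by reconciliation (branches keyed by child-node label).
- `solanaceae_ancestral_counts.tsv` — reconciled gene counts per subclass in
  the tomato-potato-pepper common ancestor.
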