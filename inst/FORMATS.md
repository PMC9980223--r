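# File formats

Tab-delimited is the canonical dialect throughout: numeric output with 6
significant digits, missing values written as `NA`, one header line. Every
file a subcommand writes is parseable by the package's own readers.

## Dosage matrix (`dosage_<role>.tsv`)

First column: sample id. Remaining columns: one per variant, header =
variant id, values = effect-allele dosages in [0, 2]. Hard calls by default;
fractional (imputed) dosages require `allow_imputed = TRUE` /
the reading context that permits them.

    sample_id	snp1	snp2
    fam1_m	0	2
    fam2_m	1	1

## Pedigree (`pedigree.tsv`)

FAM-like column order. Rows with a missing member are dropped with a warning
(incomplete trio); a child in two families is an error.

    family_id	child_id	father_id	mother_id
    fam1	fam1_c	fam1_f	fam1_m

## Phenotype / covariate table (`phenotypes.tsv`)

First column: family id. Recognised phenotype columns: `exposure_mother`,
`exposure_father`, `outcome_child`; any other column is treated as a
covariate.

    family_id	exposure_mother	exposure_father	outcome_child
    fam1	1.52	-0.33	2.10

## GWAS summary statistics

Tab-delimited with the canonical roles below; `readGwasSummary()` accepts a
column-name mapping for other dialects. `se` and `eaf` are optional.

    variant_id	chromosome	position	effect_allele	other_allele	weight	se	p_value	eaf
    rs123	1	1000000	A	G	0.021	0.003	4.1e-12	0.31

## Simulation configuration (YAML)

Keys mirror `simConfig()` arguments:

    nCouples: 4000
    nSnps: 1
    assortmentPhi: 0.9
    seed: 1

## VCF (optional)

`writeVcfDosages()` emits minimal VCFv4.2 with unphased GT per sample
(REF = other allele, ALT = effect allele); `readVcfDosages()` maps GT or DS
fields back to dosages and rejects multiallelic records.

## Provenance (`provenance.json`)

Written beside every output set: package version, timestamp, seed, and an
echo of the configuration/flags that produced the run.
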