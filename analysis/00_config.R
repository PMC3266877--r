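# Shared configuration of the synthetic discovery analysis, sourced by every
# numbered driver so all stages agree on the scenario and master seed.
#
# The scenario mirrors the emulated study design: discovery stage of 891
# cases / 3,384 controls, two replication stages (562/653 and 825/27,911),
# a 90-sample expression reference panel, and one causal cis-eQTL SNP of
# modest effect (allelic OR 1.2, expression shift 0.8 SD per allele) placed
# mid-genome so the eQTL-prioritization rule has something to find.

config <- slepipe::sim_config(
  n_cases = 891, n_controls = 3384,
  n_snps = 500, n_blocks = 50, block_ld_rho = 0.8,
  risk_snps = data.frame(snp_index = 250, allele_or = 1.2, eqtl_beta = 0.8),
  n_expr_samples = 90, probes_per_region = 5, n_decoy_regions = 40,
  seed = 20260925
)
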