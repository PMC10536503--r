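# Demonstration pipeline configuration: a simulated closed breeding
# population with a planted recessive risk locus on chromosome 3.
# Roughly 200 genotyped dogs (all cases plus 130 sampled controls from the
# last three generations) typed at 10,000 SNPs across 10 chromosomes.
simulation:
  n_generations: 4
  n_founders: 400
  sire_fraction: 0.6
  n_chromosomes: 10
  snps_per_chromosome: 1000
  snp_spacing_bp: 50000
  risk_locus:
    chr: 3
    index: 500
    freq: 0.20
  penetrance_aa: 0.7
  sporadic_rate: 0.005
  genotype_last_generations: 3
  n_genotyped_controls: 130
  seed: 2023
designs: [quantitative, binary]
prevalences: [0.1, 0.05, 0.025]
q_cutoff: 0.1
top_n_stepwise: 100
k: 10
seed: 2023
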