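# Demonstration pipeline configuration: a small synthetic community with
# one metagenome and three metatranscriptome size-fraction samples, followed
# by a Ka/Ks selection screen on simulated ortholog pairs.
seed: 1
out_dir: demo_out
simulate:
  community:
    genome_length: 50000
    n_genes: 30
    gene_length: 900
    divergence: 0.05
    gc_content: 0.35
  samples:
    - name: srf_02_3_mg
      mode: MG
      n_reads: 1500
      lineage_weights: {A: 0.8, B: 0.2}
    - name: srf_02_3_mt
      mode: MT
      n_reads: 1500
      lineage_weights: {A: 0.8, B: 0.2}
    - name: dcm_02_3_mt
      mode: MT
      n_reads: 1200
      lineage_weights: {A: 0.6, B: 0.4}
    - name: srf_5_20_mt
      mode: MT
      n_reads: 1200
      lineage_weights: {A: 0.3, B: 0.7}
filter:
  min_pident: 50
  max_evalue: 1.0e-4
  min_query_coverage: 0.90
  population_identity: 95
expression:
  mt_sample: srf_02_3_mt
  mg_sample: srf_02_3_mg
  hk_genes: [recA, gyrB]
  hk_stat: mean
selection:
  n_pairs: 12
  n_codons: 200
  omega: 0.2
  expected_dS: 0.3
  B: 200
  alpha: 0.05
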