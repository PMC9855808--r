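# Shared cohort builders for the tests.

demo_cohort <- function(n_regions = 20, edge_density = 0.15, effect_r = 0.7,
                        n_animals = 12, structure_seed = 101,
                        sample_seed = 202, transform = "softplus") {
  truth <- make_ground_truth(n_regions, edge_density, seed = structure_seed,
                             effect_r = effect_r)
  table <- simulate_cohort(truth,
                           cohort_spec(n_animals = n_animals,
                                       transform = transform),
                           seed = sample_seed)
  list(truth = truth, table = table)
}

# The study-scale configuration: 60 atlas regions, 12 animals, intermediate
# coupling on 10% of region pairs.
paper_scale_cohort <- function(structure_seed = 7, sample_seed = 11) {
  demo_cohort(n_regions = 60, edge_density = 0.1, effect_r = 0.7,
              n_animals = 12, structure_seed = structure_seed,
              sample_seed = sample_seed)
}
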