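# Study-scale fixture (2000 genes, GATAA planted at counts 0-3, effect 0.5
# lfc units per capped site, noise SD 0.5, 4 replicates per strain), built
# once and shared by the tests that exercise the full-size conditions.

big_fixture_cache <- new.env()

big_fixture <- function() {
  if (is.null(big_fixture_cache$fx)) {
    big_fixture_cache$fx <- simulate_regulon(seed = 1L, n_genes = 2000L,
                                             beta_gataa = 0.5, sigma = 0.5,
                                             replicates = 4L,
                                             plant_gyggggg = FALSE)
  }
  big_fixture_cache$fx
}

big_fixture_counts <- function() {
  if (is.null(big_fixture_cache$wcm)) {
    fx <- big_fixture()
    big_fixture_cache$wcm <- count_matrix(fx$sim$genome, fx$sim$genes,
                                          "GATAA")
  }
  big_fixture_cache$wcm
}
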