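# Shared small synthetic fixture, built once per test run. The full-size
# study fixture (2000 genes) is exercised in the acceptance tests; the
# shared one here is smaller so individual module tests stay fast.

fixture_cache <- new.env()

small_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- simulate_regulon(seed = 42L, n_genes = 120L)
  }
  fixture_cache$fx
}
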