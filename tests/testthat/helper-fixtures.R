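# Shared fixture builders; everything is generated in code at test time.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else lincae:::with_seed(seed, draw())
}

all_scheme_names <- c("DAX", "EIIP", "COMPLEMENTARY", "ENTHALPY", "GALOIS4")

tiny_layer <- function(seed = 1, d_in = 4, d_h = 3, s_f = "sigmoid",
                       s_g = "sigmoid") {
  lincae:::with_seed(seed, lincae:::init_ae_layer(d_in, d_h, s_f, s_g))
}

# a small genome with planted acceptor sites and its annotations
tiny_planted <- function(n_sites = 4, glen = 2000, seed = 5) {
  model <- motif_model("acceptor", seed = seed)
  pos <- seq(200, glen - 200, length.out = n_sites)
  plant_genome(glen, round(pos), model, seed = seed)
}
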