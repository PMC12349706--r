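# Shared fixtures built in code.

map_10_10 <- function() interval_pair_map(d1 = 10, d2 = 10)

params_poisson <- function() pathway_params(nu = 1, frac_class2 = 1)
params_interfering <- function() pathway_params(nu = 8, frac_class2 = 0)

# tetrad spore matrices from 3-bit strings
tet <- function(...) {
  s <- c(...)
  t(vapply(strsplit(s, ""), function(x) as.integer(x) == 1L, logical(3)))
}

extdata <- function(f) system.file("extdata", f, package = "tetraco")
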