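# Shared fixtures: small trees and generators used across test files.

balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
}

unit_yule <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_yule(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# default dependent-regime rates: gains of the second trait only while the
# first is in state 1 (e.g. multiple castes only in large-colony lineages)
fig5_rates <- function() {
  c(q12 = 0, q13 = 1.2, q21 = 0.5, q24 = 0.8,
    q31 = 0.8, q34 = 1.5, q42 = 0.15, q43 = 0.8)
}
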