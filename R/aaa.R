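# Seven-rank taxonomy, shallowest first.  Prefix codes follow the GTDB
# taxonomy-string convention d__;p__;c__;o__;f__;g__;s__.
.ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.rank_prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

# MIMAG assembly-quality tiers, best first; "missing" sorts last.
.quality_levels <- c("high", "medium", "low", "missing")

# Run an expression with a private RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
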