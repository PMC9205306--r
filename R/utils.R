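#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage of the pipeline (tree simulation, polytomy
#' resolution, annealer runs, ...) draws its own seed from one master seed
#' plus a stream name, so that stages can be re-run independently and a run
#' manifest listing `(master, stream)` pairs reproduces everything exactly.
#'
#' @param master integer master seed.
#' @param stream character name of the random stream.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' sub_seed(1, "spinglass")
sub_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(master)) * 7919 + h * 131) %% (2^31 - 1))
}

# internal: vertex names, falling back to indices for unnamed graphs
vertex_names <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

# internal: evaluate expr under a local, restored-on-exit RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
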