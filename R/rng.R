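# Seed management.
#
# Grid runners and power curves consume many independent random streams.
# Rather than advancing one global stream (which would make results
# depend on execution order), each unit of work draws its own substream
# seed from a hash of the root seed together with identifying values
# (grid point, scenario parameters, study label).  Hashing parameter
# values rather than loop indices means a subsetted grid run reproduces
# the matching cells of a full-grid run exactly.

MOD31 <- 2147483647  # 2^31 - 1; all arithmetic stays exact in doubles

#' Derive a reproducible substream seed
#'
#' Mixes a root seed with arbitrary identifying values (numbers or
#' strings) into an integer in `[1, 2^31 - 2]`, suitable for
#' [set.seed()].  The same root seed and values always give the same
#' substream, independent of the order in which other substreams are
#' drawn.
#'
#' @param seed Integer root seed.
#' @param ... Values identifying the unit of work (coerced to character).
#' @return A single integer seed.
#' @examples
#' substream_seed(1, "table2", 10, 0.05, 100)
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...),
                      function(v) paste(format(v, digits = 15), collapse = ","),
                      character(1)),
               collapse = "|")
  h <- (abs(as.numeric(seed)) %% MOD31) + 1
  for (k in utf8ToInt(key)) {
    h <- (h * 69621 + k + 1) %% MOD31
  }
  h <- (h * 48271) %% MOD31
  as.integer(h %% (MOD31 - 2) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
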