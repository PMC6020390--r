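# Reproducible substream seeding.
#
# Monte Carlo loops (power simulation, recovery harness, sample-size
# search) draw one independent L'Ecuyer-CMRG stream per replicate from a
# single master seed, so results do not depend on the order in which
# replicates are executed and are byte-identical for identical seeds.

substreamStates <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed) %% .Machine$integer.max,
           kind = "L'Ecuyer-CMRG")
  s <- globalenv()$.Random.seed
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

withRngState <- function(state, expr) {
  old <- globalenv()$.Random.seed
  assign(".Random.seed", state, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Deterministic integer seed derived from a master seed and an index;
# stays below 2^31 and is exact in double arithmetic.
deriveSeed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(index)) %%
               .Machine$integer.max)
}
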