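# Shared fixtures, all built in code.

# A tiny hand-built world: 10 drugs, 2 diseases, 10 proteins.  Scores are
# crafted so that for disease X drugs d1, d2 are efficacious at the
# default z cutoff (z = 2.0 each) and for disease Y only d6 is (z = 3.0).
tinyWorld <- function() {
  universe <- paste0("P", 1:10)
  drugs <- paste0("d", 1:10)
  scores <- cbind(
    X = c(5, 5, rep(0, 8)),
    Y = c(0, 0, 0, 0, 0, 5, 0, 0, 0, 0)
  )
  rownames(scores) <- drugs
  targets <- list(
    d1 = c("P1", "P2"), d2 = c("P1", "P3"), d3 = c("P9"),
    d4 = character(0), d5 = c("P10"), d6 = c("P5", "P6"),
    d7 = character(0), d8 = character(0), d9 = character(0),
    d10 = character(0)
  )
  moaWorld(scores = scores, targets = targets, universe = universe)
}

# Default study-condition world plus everything downstream, computed once
# and reused (the heavy permutation tests dominate the suite runtime).
.accCache <- new.env(parent = emptyenv())

accFixture <- function() {
  if (!is.null(.accCache$fix)) return(.accCache$fix)
  cfg <- comoaConfig(rng_seed = 1L, n_permutations = 100L)
  world <- generateWorld(worldParams(), seed = 1L)
  profiles <- suppressWarnings(inferMoaProfiles(world, cfg))
  result <- allPairs(profiles, config = cfg)
  recovery <- truthEval(world, profiles = profiles, result = result)
  .accCache$fix <- list(cfg = cfg, world = world, profiles = profiles,
                        result = result, recovery = recovery)
  .accCache$fix
}

accPermutation <- function(which) {
  key <- paste0("perm_", which)
  if (!is.null(.accCache[[key]])) return(.accCache[[key]])
  fix <- accFixture()
  .accCache[[key]] <- permutationTest(fix$world, fix$cfg, which = which,
                                      seed = 1L)
  .accCache[[key]]
}
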