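# Shared fixtures, memoized across test files (test_dir runs helpers once
# per session). Everything is generated in code; nothing is downloaded.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# the frozen synthetic training corpus (stands in for an OPM snapshot)
shared_training <- function() {
  .memo("training", sample_training_set(seed = 3))
}

shared_potential <- function() {
  .memo("potential", train_potential(shared_training()$manifest))
}

# criterion-2 toy table: one enriched type per slice, so the all-residue
# depth distribution f(s) is uniform and each type's energy is minimal and
# constant on its own band
toy_band_potential <- function() {
  .memo("toy_pot", {
    cnt <- matrix(1, 20, 32, dimnames = list(AA_CODES, NULL))
    sl_mid <- seq(-23.25, 23.25, by = 1.5)
    cnt["L", abs(sl_mid) < 12] <- 100
    cnt["W", abs(sl_mid) > 12 & abs(sl_mid) < 18] <- 100
    cnt["S", abs(sl_mid) > 18] <- 100
    potential_from_counts(cnt, kind = "alpha")
  })
}

# criterion-2 fixture: 60-residue helix whose upright pose places every
# scored residue at its type's minimal band (Gly flanks score 0 anywhere),
# so the analytic lower bound sum_i min_s E(a_i, s) is attained at (0,0,0)
perfect_helix <- function() {
  .memo("perfect_helix", {
    z_up <- (1:60 - 30.5) * 1.5
    seqv <- ifelse(abs(z_up) < 12, "L", ifelse(abs(z_up) < 18, "W", "G"))
    build_ideal_helix(seqv, tilt = 0, id = "perfect60")
  })
}

perfect_helix_bound <- function() {
  p <- toy_band_potential()
  16 * min(p$energy["L", ]) + 8 * min(p$energy["W", ])
}

# a mem_centres data.frame straight from coordinates (for geometry tests)
make_centres <- function(aa, coords, chain = "A",
                         res_seq = seq_along(aa)) {
  coords <- matrix(coords, ncol = 3)
  out <- data.frame(aa = aa, chain = chain, res_seq = res_seq, i_code = " ",
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("mem_centres", "data.frame")
  out
}

# a minimal mem_structure whose scoring centres sit at the given coords
# (CB atoms; CA for glycine)
structure_from_centres <- function(centres, id = "synthetic") {
  atoms <- data.frame(
    serial = seq_len(nrow(centres)),
    name = ifelse(centres$aa == "G", "CA", "CB"),
    alt_loc = " ",
    res_name = names(memorient:::.AA_THREE_TO_ONE)[
      match(centres$aa, memorient:::.AA_THREE_TO_ONE)],
    chain = centres$chain,
    res_seq = centres$res_seq,
    i_code = " ",
    x = centres$x, y = centres$y, z = centres$z,
    element = "C", het = FALSE, stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms), class = "mem_structure")
}

# small hand-written PDB fragment: one LEU with CA and CB
pdb_leu_lines <- function() {
  c("ATOM      1  CA  LEU A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  LEU A   1       2.000   2.500   3.500  1.00  0.00           C")
}

# independent Eq.-style oracle: plain-loop recomputation of the log-odds
# table from a count matrix (pseudocount on zero cells)
oracle_energy <- function(raw) {
  cnt <- raw
  cnt[cnt == 0] <- 1
  E <- matrix(NA_real_, nrow(cnt), ncol(cnt))
  total <- sum(cnt)
  for (a in seq_len(nrow(cnt))) {
    for (s in seq_len(ncol(cnt))) {
      f_a <- cnt[a, s] / sum(cnt[a, ])
      f <- sum(cnt[, s]) / total
      E[a, s] <- -log(f_a / f)
    }
  }
  E
}

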