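## thickness: hydrophobic membrane thickness from a split potential.
##
## For an already-oriented structure, the two head-group regions of the
## potential (10 <= z <= 20 and -20 <= z <= -10) are translated outward
## independently. A residue whose depth falls inside a shifted window is
## scored by the depth-sliced potential at the back-shifted depth;
## residues between the windows take their type's core average energy and
## residues beyond them the extramembranous average. The offset pair with
## the lowest total energy gives the thickness estimate as
## 30 + offset_upper + offset_lower (the distance between window
## midpoints; at rest they sit at +/-15 A, the standard hydrophobic
## thickness of 30 A).

.HEAD_LO <- 10
.HEAD_HI <- 20

#' Split-potential energy under head-group offsets
#'
#' @param p A `mem_potential`.
#' @param centres A `mem_centres` data.frame of an oriented structure.
#' @param offset_upper,offset_lower Signed window translations, A;
#'   positive moves the window outward (away from z = 0).
#' @param max_offset Permitted offset magnitude, A.
#' @return Scalar energy.
#' @export
split_energy <- function(p, centres, offset_upper = 0, offset_lower = 0,
                         max_offset = 8) {
  stopifnot(inherits(p, "mem_potential"))
  if (abs(offset_upper) > max_offset || abs(offset_lower) > max_offset) {
    stop("offset outside permitted range of +/-", max_offset, " A")
  }
  z <- centres$z
  idx <- .aa_index(centres$aa)
  e <- numeric(length(z))

  up <- z >= .HEAD_LO + offset_upper & z <= .HEAD_HI + offset_upper
  lo <- z <= -(.HEAD_LO + offset_lower) & z >= -(.HEAD_HI + offset_lower)
  core <- !up & !lo & z > -(.HEAD_LO + offset_lower) & z < .HEAD_LO + offset_upper
  outer <- !up & !lo & !core

  if (any(up)) e[up] <- residue_energy(p, centres$aa[up], z[up] - offset_upper)
  if (any(lo)) e[lo] <- residue_energy(p, centres$aa[lo], z[lo] + offset_lower)
  if (any(core)) e[core] <- p$core_avg[idx[core]]
  if (any(outer)) e[outer] <- p$extramem_avg[idx[outer]]
  sum(e)
}

#' Estimate hydrophobic membrane thickness
#'
#' Exhaustive scan of both head-group offsets on a step grid; the lowest
#' split energy wins. Ties are broken by the smallest total |offset|, then
#' lexicographically.
#'
#' @param p A `mem_potential`.
#' @param s An oriented `mem_structure` (membrane normal = z), or a
#'   `mem_centres` data.frame.
#' @param step Scan step, A (default 0.25).
#' @param range Scan half-range per leaflet, A (default 8).
#' @return List of class `mem_thickness` with `thickness`, `offset_upper`,
#'   `offset_lower`, `energy`.
#' @export
estimate_thickness <- function(p, s, step = 0.25, range = 8) {
  centres <- if (inherits(s, "mem_centres")) s else scoring_centres(s, quiet = TRUE)
  offs <- seq(-range, range, by = step)
  grid <- expand.grid(lower = offs, upper = offs)  # upper slowest: lexicographic
  e <- mapply(function(u, l) split_energy(p, centres, u, l, max_offset = range),
              grid$upper, grid$lower)
  best_e <- min(e)
  tie <- which(e <= best_e + 1e-12)
  o <- tie[order(abs(grid$upper[tie]) + abs(grid$lower[tie]),
                 grid$upper[tie], grid$lower[tie])][1]
  structure(list(thickness = 30 + grid$upper[o] + grid$lower[o],
                 offset_upper = grid$upper[o], offset_lower = grid$lower[o],
                 energy = e[o]),
            class = "mem_thickness")
}

#' @export
print.mem_thickness <- function(x, ...) {
  cat(sprintf("<mem_thickness %.2f A (offsets upper %+.2f, lower %+.2f; E=%.4f)>\n",
              x$thickness, x$offset_upper, x$offset_lower, x$energy))
  invisible(x)
}
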