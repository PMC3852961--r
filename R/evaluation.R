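## evaluation: tilt angles, z-shifts, naive orientation, comparisons
## against reference orientations, and lipid-vector tilts.

#' Read a transmembrane topology annotation
#'
#' Tab/whitespace-separated file with columns `chain start end sense`,
#' `#`-comments allowed. `sense` is `in-out` or `out-in` (case
#' insensitive; `IN->OUT` style accepted). When the sense column is
#' absent, segments alternate starting `in-out` per chain.
#'
#' @param file Path or character vector of lines.
#' @return Data.frame of class `mem_topology` with columns `chain`,
#'   `start`, `end`, `sense`.
#' @export
read_topology <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else file
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty topology file")
  parts <- strsplit(lines, "\\s+")
  n <- lengths(parts)
  if (any(n < 3L)) stop("topology lines need at least: chain start end")
  topo <- data.frame(
    chain = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    end = as.integer(vapply(parts, `[[`, character(1), 3)),
    sense = vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_,
                   character(1)),
    stringsAsFactors = FALSE
  )
  topo$sense <- tolower(gsub("->", "-", topo$sense))
  topo$sense[topo$sense %in% c("inout", "in_out")] <- "in-out"
  topo$sense[topo$sense %in% c("outin", "out_in")] <- "out-in"
  # absent sense: alternate per chain starting in-out
  for (ch in unique(topo$chain)) {
    i <- which(topo$chain == ch)
    miss <- is.na(topo$sense[i])
    if (any(miss)) {
      topo$sense[i] <- rep(c("in-out", "out-in"), length.out = length(i))
    }
  }
  if (!all(topo$sense %in% c("in-out", "out-in"))) {
    stop("sense must be in-out or out-in")
  }
  topology(topo$chain, topo$start, topo$end, topo$sense)
}

#' Construct a topology annotation
#'
#' @param chain,start,end,sense Parallel vectors describing one
#'   transmembrane segment per element; `sense` is `"in-out"` or
#'   `"out-in"` (the direction the segment crosses the membrane, cytoplasm
#'   being "in").
#' @return Data.frame of class `mem_topology`.
#' @export
topology <- function(chain, start, end, sense = "in-out") {
  topo <- data.frame(chain = as.character(chain), start = as.integer(start),
                     end = as.integer(end),
                     sense = rep_len(sense, length(chain)),
                     stringsAsFactors = FALSE)
  stopifnot(all(topo$start < topo$end),
            all(topo$sense %in% c("in-out", "out-in")))
  for (ch in unique(topo$chain)) {
    seg <- topo[topo$chain == ch, ]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop("overlapping segments in chain ", ch)
    }
  }
  class(topo) <- c("mem_topology", "data.frame")
  topo
}

#' Write a topology annotation to a TSV file
#'
#' @param topo A `mem_topology`.
#' @param file Path.
#' @export
write_topology <- function(topo, file) {
  writeLines(c("# chain\tstart\tend\tsense",
               sprintf("%s\t%d\t%d\t%s", topo$chain, topo$start, topo$end,
                       topo$sense)), file)
}

# scoring centre of one residue, or NULL
.centre_of <- function(centres, chain, res_seq) {
  i <- which(centres$chain == chain & centres$res_seq == res_seq)
  if (!length(i)) return(NULL)
  c(centres$x[i[1]], centres$y[i[1]], centres$z[i[1]])
}

# per-segment vectors, flipped so each points in->out; rows are segments
.segment_vectors <- function(s, topo, flip_sense = TRUE) {
  centres <- if (inherits(s, "mem_centres")) s else scoring_centres(s, quiet = TRUE)
  vecs <- matrix(NA_real_, nrow(topo), 3)
  for (i in seq_len(nrow(topo))) {
    a <- .centre_of(centres, topo$chain[i], topo$start[i])
    b <- .centre_of(centres, topo$chain[i], topo$end[i])
    if (is.null(a) || is.null(b)) {
      warning("segment ", i, ": boundary residue missing, skipped")
      next
    }
    v <- b - a
    if (flip_sense && topo$sense[i] == "out-in") v <- -v
    vecs[i, ] <- v
  }
  vecs <- vecs[stats::complete.cases(vecs), , drop = FALSE]
  if (!nrow(vecs)) stop("no usable transmembrane segments")
  vecs
}

#' Longitudinal axis of a transmembrane protein
#'
#' The normalised vector average of all transmembrane segment vectors
#' (boundary scoring centre to boundary scoring centre), each flipped so
#' its annotated sense points in->out (+z in the reference frame).
#'
#' @param s A `mem_structure` or `mem_centres`.
#' @param topo A `mem_topology`.
#' @return Unit 3-vector.
#' @export
longitudinal_axis <- function(s, topo) {
  vecs <- .segment_vectors(s, topo)
  vecs <- vecs / sqrt(rowSums(vecs^2))
  m <- colMeans(vecs)
  len <- sqrt(sum(m^2))
  if (len < 1e-9) stop("degenerate axis")
  m / len
}

#' Tilt angle of an axis from the membrane normal
#'
#' `acos(|axis . z|)` in degrees, folded into \[0, 90\]: only the
#' magnitude of the tilt is reported.
#'
#' @param axis Unit 3-vector.
#' @return Degrees in \[0, 90\].
#' @export
tilt_angle <- function(axis) {
  acos(min(1, abs(axis[3]) / sqrt(sum(axis^2)))) * 180 / pi
}

#' Mean absolute tilt of all transmembrane segments
#'
#' @param s A `mem_structure` or `mem_centres`.
#' @param topo A `mem_topology`.
#' @return Degrees.
#' @export
mean_segment_tilt <- function(s, topo) {
  vecs <- .segment_vectors(s, topo)
  mean(apply(vecs, 1, tilt_angle))
}

#' Mean z-coordinate of transmembrane segment boundary residues
#'
#' @param s A `mem_structure` or `mem_centres`.
#' @param topo A `mem_topology`.
#' @return Mean z, A.
#' @export
z_shift <- function(s, topo) {
  centres <- if (inherits(s, "mem_centres")) s else scoring_centres(s, quiet = TRUE)
  zs <- c()
  for (i in seq_len(nrow(topo))) {
    for (r in c(topo$start[i], topo$end[i])) {
      p <- .centre_of(centres, topo$chain[i], r)
      if (is.null(p)) warning("boundary residue ", topo$chain[i], r,
                              " missing, skipped")
      else zs <- c(zs, p[3])
    }
  }
  if (!length(zs)) stop("no usable boundary residues")
  mean(zs)
}

#' Naive orientation from topology alone
#'
#' Tilts the structure so the longitudinal axis is parallel to z, then
#' translates so the mean boundary-residue z-coordinate is zero. The
#' baseline the potential-based search is compared against.
#'
#' @param s A `mem_structure`.
#' @param topo A `mem_topology`.
#' @return A `mem_transform`.
#' @export
naive_orient <- function(s, topo) {
  v <- longitudinal_axis(s, topo)
  # R_x(a) takes v into the xz-plane, R_y(b) takes the result to +z
  a <- atan2(v[2], v[3])
  zp <- sin(a) * v[2] + cos(a) * v[3]
  b <- atan2(-v[1], zp)
  rot <- transform_pose(a * 180 / pi, b * 180 / pi, 0)
  centres <- scoring_centres(s, quiet = TRUE)
  xyz <- apply_transform(cbind(centres$x, centres$y, centres$z), rot)
  centres$x <- xyz[, 1]; centres$y <- xyz[, 2]; centres$z <- xyz[, 3]
  transform_pose(rot$rot_x, rot$rot_y, -z_shift(centres, topo))
}

#' Compare a test orientation against a reference
#'
#' @param test,ref `mem_structure`s with the same residue content.
#' @param topo A `mem_topology` valid for both.
#' @param ref_error Length-2 numeric: the reference's published error
#'   margin as (tilt degrees, z-shift A).
#' @return List of class `mem_comparison` with `tilt_delta` (degrees, in
#'   \[0, 90\]), `z_delta` (A), `within_error` (logical).
#' @export
compare_orientations <- function(test, ref, topo, ref_error = c(3, 1)) {
  tc <- scoring_centres(test, quiet = TRUE)
  rc <- scoring_centres(ref, quiet = TRUE)
  if (nrow(tc) != nrow(rc) ||
      !all(paste(tc$chain, tc$res_seq, tc$aa) == paste(rc$chain, rc$res_seq, rc$aa))) {
    stop("test and reference structures have mismatched residues")
  }
  va <- longitudinal_axis(tc, topo)
  vb <- longitudinal_axis(rc, topo)
  tilt_delta <- acos(min(1, abs(sum(va * vb)))) * 180 / pi
  z_delta <- abs(z_shift(tc, topo) - z_shift(rc, topo))
  structure(list(tilt_delta = tilt_delta, z_delta = z_delta,
                 within_error = tilt_delta <= ref_error[1] &&
                   z_delta <= ref_error[2]),
            class = "mem_comparison")
}

#' @export
print.mem_comparison <- function(x, ...) {
  cat(sprintf("<mem_comparison tilt_delta=%.2f deg z_delta=%.2f A %s>\n",
              x$tilt_delta, x$z_delta,
              if (x$within_error) "within error" else "outside error"))
  invisible(x)
}

#' Average lipid-vector tilt in one leaflet
#'
#' For each hetero (lipid) molecule in the requested leaflet (assigned by
#' the sign of its mean z), the vector from its first to its last carbon
#' atom in PDB atom order is taken; the per-lipid unit vectors are
#' averaged, normalised, and the tilt from z reported.
#'
#' @param s A `mem_structure` containing HETATM lipid molecules.
#' @param leaflet `"upper"` (z > 0) or `"lower"` (cytoplasmic, z < 0).
#' @return Degrees in \[0, 90\].
#' @export
lipid_vector_tilt <- function(s, leaflet = c("lower", "upper")) {
  leaflet <- match.arg(leaflet)
  het <- s$atoms[s$atoms$het, , drop = FALSE]
  if (!nrow(het)) stop("no lipid (HETATM) molecules in structure")
  carbons <- het[het$element == "C" | (het$element == "" & grepl("^C", het$name)), ,
                 drop = FALSE]
  key <- paste(carbons$chain, carbons$res_seq, carbons$res_name)
  vecs <- NULL
  for (k in unique(key)) {
    m <- carbons[key == k, , drop = FALSE]
    if (nrow(m) < 2L) next
    in_lower <- mean(m$z) < 0
    if ((leaflet == "lower") != in_lower) next
    v <- c(m$x[nrow(m)] - m$x[1], m$y[nrow(m)] - m$y[1], m$z[nrow(m)] - m$z[1])
    n <- sqrt(sum(v^2))
    if (n < 1e-9) next
    vecs <- rbind(vecs, v / n)
  }
  if (is.null(vecs)) stop("no lipid with >= 2 carbon atoms in ", leaflet,
                          " leaflet")
  m <- colMeans(vecs)
  tilt_angle(m / sqrt(sum(m^2)))
}
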