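## potential: the depth-sliced log-odds membrane potential.
##
## The membrane is an infinite slab 48 A thick, divided along z into 32
## slices of 1.5 A (roughly the rise per residue of an alpha helix), with
## z = 0 at the membrane centre and the cytoplasm at negative z. Training
## counts the scoring centre (CB; CA for glycine) of every residue per
## slice; the pseudo-energy of type a in slice z is
##
##     E_a(z) = -ln( f_a(z) / f(z) )
##
## where f_a(z) is the relative frequency of type a at depth z (normalised
## over depth within the type) and f(z) the relative frequency of all
## residues at depth z. A pseudocount of one is added to any (type, slice)
## cell with zero observations so every energy is finite.

#' The depth-slice grid of the membrane slab
#'
#' @param half_thickness Half the slab thickness, A.
#' @param n_slices Number of slices.
#' @return List of class `mem_grid` with fields `half_thickness`,
#'   `n_slices`, `slice_width`.
#' @export
slice_grid <- function(half_thickness = 24, n_slices = 32) {
  sw <- 2 * half_thickness / n_slices
  structure(list(half_thickness = half_thickness, n_slices = n_slices,
                 slice_width = sw), class = "mem_grid")
}

#' Map a depth to its slice index
#'
#' Slices are half-open `[lo, lo + width)` starting at `z = -half_thickness`;
#' index 1 is the slice touching the lower (cytoplasmic) face. Depths
#' outside the slab map to `NA` ("outside").
#'
#' @param z Numeric depth(s), A.
#' @param grid A `mem_grid`.
#' @return Integer slice indices in `1..n_slices`, `NA` outside the slab.
#' @export
slice_index <- function(z, grid = slice_grid()) {
  if (any(!is.finite(z))) stop("non-finite depth")
  idx <- floor((z + grid$half_thickness) / grid$slice_width) + 1L
  idx[z < -grid$half_thickness | z >= grid$half_thickness] <- NA_integer_
  as.integer(idx)
}

# midpoints of the slices, A
.slice_mid <- function(grid) {
  -grid$half_thickness + (seq_len(grid$n_slices) - 0.5) * grid$slice_width
}

#' Build a potential table from per-slice counts
#'
#' Applies the pseudocount rule, normalises, and takes the negative log
#' ratio. The per-type core and extramembranous averages used by the
#' thickness module are the means of each type's energies over the slices
#' whose midpoints satisfy |z| < 10 A and |z| > 19.5 A respectively.
#'
#' @param counts 20 x n_slices matrix of raw observation counts, rows in
#'   [AA_CODES] order.
#' @param grid A `mem_grid`.
#' @param kind "alpha" or "beta".
#' @param meta Optional named list of training metadata.
#' @param pseudocount "zero-cells" adds 1 only where a cell is zero (the
#'   default); "everywhere" adds 1 to every cell (sensitivity analysis).
#' @return Object of class `mem_potential` with fields `grid`, `counts`
#'   (post-pseudocount), `energy` (20 x n_slices), `core_avg`,
#'   `extramem_avg` (named per-type vectors), `kind`, `meta`.
#' @export
potential_from_counts <- function(counts, grid = slice_grid(),
                                  kind = c("alpha", "beta"),
                                  meta = list(),
                                  pseudocount = c("zero-cells", "everywhere")) {
  kind <- match.arg(kind)
  pseudocount <- match.arg(pseudocount)
  counts <- as.matrix(counts)
  if (nrow(counts) != 20L || ncol(counts) != grid$n_slices) {
    stop("counts must be 20 x ", grid$n_slices)
  }
  if (pseudocount == "everywhere") {
    counts <- counts + 1
  } else {
    counts[counts == 0] <- 1
  }
  f_a <- counts / rowSums(counts)              # per-type depth distribution
  f <- colSums(counts) / sum(counts)           # all-residue depth distribution
  energy <- -log(sweep(f_a, 2, f, "/"))
  dimnames(counts) <- dimnames(energy) <- list(AA_CODES, NULL)

  mid <- .slice_mid(grid)
  core <- abs(mid) < 10
  extra <- abs(mid) > grid$half_thickness - 4.5   # outermost 3 slices each side
  pot <- structure(list(
    grid = grid, counts = counts, energy = energy,
    core_avg = rowMeans(energy[, core, drop = FALSE]),
    extramem_avg = rowMeans(energy[, extra, drop = FALSE]),
    kind = kind, meta = meta, pseudocount = pseudocount
  ), class = "mem_potential")
  pot
}

#' @export
print.mem_potential <- function(x, ...) {
  cat(sprintf("<mem_potential kind=%s  %d x %d  (slab %g A, slice %g A)>\n",
              x$kind, nrow(x$energy), ncol(x$energy),
              2 * x$grid$half_thickness, x$grid$slice_width))
  invisible(x)
}

#' Count scoring centres per (type, slice) for pre-oriented structures
#'
#' @param structures List of `mem_structure`, pre-oriented (membrane
#'   normal = z, centre at z = 0, cytoplasm at negative z).
#' @param grid A `mem_grid`.
#' @return 20 x n_slices matrix of raw counts.
#' @export
count_centres <- function(structures, grid = slice_grid()) {
  counts <- matrix(0, 20L, grid$n_slices)
  for (s in structures) {
    cen <- scoring_centres(s, quiet = TRUE)
    idx <- slice_index(cen$z, grid)
    ok <- !is.na(idx)
    if (!any(ok)) next
    tab <- table(factor(cen$aa[ok], levels = AA_CODES), factor(idx[ok], levels = seq_len(grid$n_slices)))
    counts <- counts + as.matrix(tab)
  }
  counts
}

#' Train the membrane potential from a manifest of pre-oriented structures
#'
#' Entries can be excluded explicitly by id, and cross-validation style by
#' superfamily label or by listed high-identity partners of a target:
#' when `target` is given, every entry sharing its superfamily label and
#' every entry listing the target among its identity partners (>25%
#' sequence identity, precomputed upstream) is dropped.
#'
#' @param manifest Data.frame with columns `id`, `path` (PDB file),
#'   optional `chains` (comma-separated), `kind`, `resolution` (A),
#'   `superfamily`, `identity_partners` (comma-separated ids).
#'   Alternatively a column `structure` may hold `mem_structure` objects
#'   directly (list-column), in which case `path` is ignored.
#' @param kind Potential flavour, "alpha" or "beta".
#' @param resolution_cutoff Maximum resolution retained, A (default 3.5).
#' @param exclude_ids Character ids dropped from training.
#' @param target Optional target id triggering superfamily/identity
#'   exclusion.
#' @param grid A `mem_grid`.
#' @param pseudocount See [potential_from_counts()].
#' @return A `mem_potential`.
#' @export
train_potential <- function(manifest, kind = c("alpha", "beta"),
                            resolution_cutoff = 3.5,
                            exclude_ids = character(),
                            target = NULL,
                            grid = slice_grid(),
                            pseudocount = c("zero-cells", "everywhere")) {
  kind <- match.arg(kind)
  m <- manifest
  if (!is.null(m$resolution)) m <- m[m$resolution <= resolution_cutoff, , drop = FALSE]
  if (!is.null(m$kind)) m <- m[m$kind == kind, , drop = FALSE]
  drop <- m$id %in% exclude_ids
  if (!is.null(target)) {
    drop <- drop | m$id == target
    if (!is.null(m$superfamily)) {
      fam <- m$superfamily[manifest$id == target]
      if (length(fam) == 1L && nzchar(fam)) drop <- drop | m$superfamily == fam
    }
    if (!is.null(m$identity_partners)) {
      partners <- strsplit(ifelse(is.na(m$identity_partners), "",
                                  m$identity_partners), ",")
      drop <- drop | vapply(partners, function(p) target %in% trimws(p), logical(1))
    }
  }
  m <- m[!drop, , drop = FALSE]
  if (!nrow(m)) stop("empty training set after exclusions")

  structures <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!is.null(m$structure)) {
      structures[[i]] <- m$structure[[i]]
    } else {
      ch <- NULL
      if (!is.null(m$chains) && !is.na(m$chains[i]) && nzchar(m$chains[i])) {
        ch <- trimws(strsplit(m$chains[i], ",")[[1]])
      }
      structures[[i]] <- tryCatch(read_structure(m$path[i], chains = ch),
                                  error = function(e) {
                                    warning("skipping ", m$id[i], ": ",
                                            conditionMessage(e))
                                    NULL
                                  })
    }
  }
  structures <- Filter(Negate(is.null), structures)
  if (!length(structures)) stop("empty training set: no readable structures")

  potential_from_counts(count_centres(structures, grid), grid = grid,
                        kind = kind,
                        meta = list(n_structures = length(structures),
                                    ids = m$id,
                                    resolution_cutoff = resolution_cutoff),
                        pseudocount = pseudocount)
}

#' Pseudo-energy of one residue type at a depth
#'
#' Returns 0 outside the slab: the slab is the potential's entire support,
#' so extramembranous residues do not contribute to orientation energy.
#'
#' @param p A `mem_potential`.
#' @param aa One-letter code(s).
#' @param z Depth(s), A.
#' @return Numeric energies.
#' @export
residue_energy <- function(p, aa, z) {
  stopifnot(inherits(p, "mem_potential"))
  idx <- .aa_index(aa)
  s <- slice_index(z, p$grid)
  e <- numeric(length(z))
  ok <- !is.na(s)
  e[ok] <- p$energy[cbind(rep_len(idx, length(z))[ok], s[ok])]
  e
}

#' Total pseudo-energy of a structure's scoring centres under a pose
#'
#' The sum over scoring centres of the slice energy at each transformed
#' depth. Residues transformed outside the slab contribute zero.
#'
#' @param p A `mem_potential`.
#' @param centres A `mem_centres` data.frame (see [scoring_centres()]).
#' @param t A `mem_transform` (default identity).
#' @return Scalar energy.
#' @export
structure_energy <- function(p, centres, t = transform_pose(0, 0, 0)) {
  stopifnot(inherits(p, "mem_potential"), nrow(centres) >= 1L)
  cm <- .centres_matrix(centres)
  pose_energies_cpp(cm$coords, cm$aa, p$energy, t$rot_x, t$rot_y, t$dz,
                    p$grid$half_thickness, p$grid$slice_width)[1]
}

# vectorised over poses; used by all search methods
.pose_energies <- function(p, cm, rx, ry, dz) {
  pose_energies_cpp(cm$coords, cm$aa, p$energy, rx, ry, dz,
                    p$grid$half_thickness, p$grid$slice_width)
}

#' Serialize a potential to plain text
#'
#' Format: header lines `#kind`, `#grid <n_slices> <slice_width>`,
#' `#resolution`, `#pseudocount`, then 20 rows of n_slices counts (rows in
#' [AA_CODES] order), a literal `#energies` line, and 20 rows of energies.
#' Energies are recomputed from the counts on load and checked against the
#' stored values.
#'
#' @param p A `mem_potential`.
#' @param file Optional path to write to.
#' @return Invisibly, the character vector of lines.
#' @export
save_potential <- function(p, file = NULL) {
  stopifnot(inherits(p, "mem_potential"))
  res <- p$meta$resolution_cutoff
  lines <- c(
    paste("#kind", p$kind),
    sprintf("#grid %d %g", p$grid$n_slices, p$grid$slice_width),
    paste("#resolution", if (is.null(res)) "NA" else format(res)),
    paste("#pseudocount", p$pseudocount),
    apply(p$counts, 1, paste, collapse = " "),
    "#energies",
    apply(format(p$energy, digits = 17, scientific = TRUE, trim = TRUE),
          1, paste, collapse = " ")
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Load a potential from its text serialization
#'
#' @param file Path to a potential file, or a character vector of lines.
#' @return A `mem_potential`.
#' @export
load_potential <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else file
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)
    if (!length(ln)) stop("potential file missing #", key, " header")
    trimws(sub(paste0("^#", key, " "), "", ln[1]))
  }
  kind <- hdr("kind")
  g <- as.numeric(strsplit(hdr("grid"), "\\s+")[[1]])
  if (length(g) != 2L || any(!is.finite(g))) stop("malformed #grid header")
  grid <- slice_grid(half_thickness = g[1] * g[2] / 2, n_slices = g[1])
  res <- suppressWarnings(as.numeric(hdr("resolution")))
  pc <- hdr("pseudocount")

  body <- lines[!grepl("^#", lines) | lines == "#energies"]
  esep <- which(body == "#energies")
  if (length(esep) != 1L) stop("potential file missing #energies section")
  parse_rows <- function(rows, what) {
    if (length(rows) != 20L) {
      stop("potential file shape error: expected 20 ", what, " rows, got ",
           length(rows))
    }
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(lengths(vals) != grid$n_slices)) {
      stop("potential file shape error: ", what, " row width != ",
           grid$n_slices)
    }
    do.call(rbind, vals)
  }
  counts <- parse_rows(body[seq_len(esep - 1L)], "count")
  energy <- parse_rows(body[(esep + 1L):length(body)], "energy")

  p <- potential_from_counts(counts, grid = grid, kind = kind,
                             meta = list(resolution_cutoff = res),
                             pseudocount = "zero-cells")
  p$pseudocount <- pc
  if (max(abs(p$energy - energy)) > 1e-9) {
    stop("potential file corrupt: stored energies do not match recomputed")
  }
  p
}
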