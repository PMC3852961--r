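## synthetic: idealized pre-oriented transmembrane structures with
## controlled residue-depth statistics. Stands in for an OPM-style
## training snapshot so that training, orientation, thickness and decoy
## modules are exercised end to end with no downloads.
##
## Geometry: a canonical alpha helix as a C-alpha trace (2.3 A radius,
## 100 degrees twist and 1.5 A rise per residue) with C-beta placed 1.53 A
## radially outward (glycine gets no C-beta). Default helices are 51
## residues (75 A span): long enough that the extramembranous flanks
## anchor the z-registration the way real juxtamembrane regions do. For
## helix lengths with (n-1)*100 = 0 mod 360 (19, 37, 55, ...) the two
## boundary residues share their azimuth and the boundary-to-boundary
## segment vector is exactly parallel to the helix axis; other lengths
## carry a sub-0.1-degree azimuthal bias in segment tilt.

.CA_RADIUS <- 2.3
.CB_OFFSET <- 1.53
.HELIX_RISE <- 1.5
.HELIX_TWIST <- 100

#' Build an idealized transmembrane helix
#'
#' A C-alpha/C-beta helix along z, centred at z = 0, then tilted about the
#' x axis and shifted along z. The accompanying topology annotation is a
#' single segment spanning the sequence; a helix built ascending in z has
#' sense `in-out` (cytoplasm at negative z).
#'
#' @param sequence One-letter amino-acid string (or character vector),
#'   length >= 5.
#' @param tilt Tilt from the membrane normal, degrees.
#' @param z_offset Translation along z, A.
#' @param chain Chain identifier.
#' @param res_start First residue number.
#' @param descending Build the helix descending in z (sense `out-in`).
#' @param xy Lateral offset of the helix axis, length-2 numeric, A.
#' @param id Structure id.
#' @return List with `structure` (a `mem_structure`) and `topology`
#'   (a `mem_topology` with one segment).
#' @export
build_ideal_helix <- function(sequence, tilt = 0, z_offset = 0, chain = "A",
                              res_start = 1L, descending = FALSE,
                              xy = c(0, 0), id = "helix") {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  n <- length(aa)
  stopifnot(n >= 5L, all(aa %in% AA_CODES))
  three <- names(.AA_THREE_TO_ONE)[match(aa, .AA_THREE_TO_ONE)]

  i <- seq_len(n) - 1
  phase <- i * .HELIX_TWIST * pi / 180
  zs <- (i - (n - 1) / 2) * .HELIX_RISE
  if (descending) zs <- -zs
  ca <- cbind(.CA_RADIUS * cos(phase) + xy[1],
              .CA_RADIUS * sin(phase) + xy[2], zs)
  cb <- cbind((.CA_RADIUS + .CB_OFFSET) * cos(phase) + xy[1],
              (.CA_RADIUS + .CB_OFFSET) * sin(phase) + xy[2], zs)

  # interleave CA/CB rows, dropping CB for glycine
  keep_cb <- aa != "G"
  ord <- order(rep(seq_len(n), 2), rep(1:2, each = n))
  atoms <- data.frame(
    serial = 0L,
    name = rep(c("CA", "CB"), each = n)[ord],
    alt_loc = " ",
    res_name = rep(three, 2)[ord],
    chain = chain,
    res_seq = rep(res_start + seq_len(n) - 1L, 2)[ord],
    i_code = " ",
    x = c(ca[, 1], cb[, 1])[ord], y = c(ca[, 2], cb[, 2])[ord],
    z = c(ca[, 3], cb[, 3])[ord],
    element = "C", het = FALSE, stringsAsFactors = FALSE)
  atoms <- atoms[c(rep(TRUE, n), keep_cb)[ord], , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  s <- structure(list(id = id, atoms = atoms), class = "mem_structure")
  if (tilt != 0 || z_offset != 0) {
    s <- transform_structure(s, transform_pose(tilt, 0, z_offset))
  }
  topo <- topology(chain, res_start, res_start + n - 1L,
                   if (descending) "out-in" else "in-out")
  list(structure = s, topology = topo)
}

#' Depth-dependent residue composition specification
#'
#' Encodes the qualitative biology the membrane potential captures:
#' hydrophobics enriched in the hydrocarbon core, aromatics in the lipid
#' head-group bands, lysine/arginine on the cytoplasmic flank
#' (positive-inside asymmetry), and polar/charged types outside the
#' membrane. Zone boundaries scale with `core_half_width` so thicker or
#' thinner synthetic membranes can be emulated. Magnitudes are test
#' constants, not measured values.
#'
#' @param core_half_width Half-width of the hydrophobic core, A
#'   (default 15, matching the 30 A standard hydrophobic thickness).
#' @param enrichment Multiplier applied inside each zone.
#' @param noise Mixing weight toward a depth-independent composition,
#'   in \[0, 1\].
#' @param background Named length-20 composition; default uniform.
#' @return List of class `mem_depth_spec`.
#' @export
depth_spec <- function(core_half_width = 15, enrichment = 8, noise = 0.1,
                       background = NULL) {
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA_CODES)
  stopifnot(core_half_width > 0, enrichment > 0, noise >= 0, noise <= 1,
            all(background > 0))
  structure(list(core_half_width = core_half_width, enrichment = enrichment,
                 noise = noise, background = background[AA_CODES]),
            class = "mem_depth_spec")
}

# P(aa | depth z): 20 x length(z) matrix of sampling probabilities
.depth_probs <- function(spec, z) {
  sc <- 15 / spec$core_half_width   # map real depth onto the template zones
  zt <- z * sc
  e <- spec$enrichment
  w <- matrix(1, 20, length(z), dimnames = list(AA_CODES, NULL))
  # four bands: aliphatics across the hydrocarbon core, the aromatic belt
  # (Trp/Tyr) at the inner head-group region with Lys/Arg piled on the
  # cytoplasmic side (positive-inside rule), interface-polar types at the
  # outer head-group region near the phosphates, and charged types
  # outside. The sharp boundaries anchor orientation and membrane
  # thickness: any depth rescaling or head-group window shift pushes
  # residues across a band edge at a cost. Band edges sit on 1.5 A slice
  # boundaries (10.5 / 15 / 19.5 A) so that, at the reference core width,
  # no potential slice straddles two bands -- otherwise a sub-slice rigid
  # shift of a test structure gains energy purely by re-registering band
  # edges against slice edges. The core is deliberately flat (one band):
  # a depth-structured core would make the thickness module's flat core
  # average exploitable by widening the head-group windows inward.
  core <- abs(zt) <= 10.5
  head_in <- abs(zt) > 10.5 & abs(zt) <= 15
  head_out <- abs(zt) > 15 & abs(zt) <= 19.5
  outside <- abs(zt) > 19.5
  cyto_head <- zt < -10.5 & zt >= -19.5
  w[c("A", "F", "I", "L", "M", "V"), core] <- e
  w[c("W", "Y"), head_in] <- e
  w[c("N", "Q", "H", "S", "T"), head_out] <- e
  w[c("K", "R"), cyto_head] <- 1.5 * e
  w[c("D", "E"), outside] <- e
  pr <- w * spec$background
  pr <- sweep(pr, 2, colSums(pr), "/")
  u <- spec$background / sum(spec$background)
  (1 - spec$noise) * pr + spec$noise * u
}

# sequence sampled residue-by-residue from the depth profile
# (vectorised inverse-CDF draw, one uniform per residue)
.sample_sequence <- function(spec, z) {
  pr <- .depth_probs(spec, z)
  cs <- apply(pr, 2, cumsum)
  u <- runif(length(z)) * cs[20, ]
  AA_CODES[colSums(sweep(cs, 2, u, "<")) + 1L]
}

# depths of an n-residue helix placed like build_ideal_helix
.helix_depths <- function(n, z_offset = 0, descending = FALSE) {
  zs <- (seq_len(n) - 1 - (n - 1) / 2) * .HELIX_RISE
  if (descending) zs <- -zs
  zs + z_offset
}

#' Build a multi-helix bundle with depth-sampled residue types
#'
#' Antiparallel helices on a circle, with residue identities drawn from
#' the depth profile at each residue's depth *in the final placement*:
#' the geometry is built, tilted by `tilt` and shifted by `z_offset`
#' first, and types are then sampled at the resulting scoring-centre
#' depths. The constructed pose is therefore the energy optimum of a
#' potential trained on matching fixtures, which is what the
#' orientation-recovery tests rely on.
#'
#' @param spec A `mem_depth_spec`.
#' @param n_helices Number of helices.
#' @param n_res Residues per helix (see module notes).
#' @param tilt,z_offset Rigid placement of the bundle.
#' @param id Structure id.
#' @return List with `structure` and `topology` (one segment per helix,
#'   alternating sense).
#' @export
build_bundle <- function(spec = depth_spec(), n_helices = 6, n_res = 51,
                         tilt = 0, z_offset = 0, id = "bundle") {
  ring_r <- max(6, 1.8 * n_helices)
  helices <- vector("list", n_helices)
  topo <- NULL
  for (j in seq_len(n_helices)) {
    desc <- j %% 2 == 0
    ang <- 2 * pi * (j - 1) / n_helices
    h <- build_ideal_helix(rep("A", n_res), chain = "A",
                           res_start = (j - 1L) * n_res + 1L,
                           descending = desc,
                           xy = ring_r * c(cos(ang), sin(ang)), id = id)
    helices[[j]] <- h$structure$atoms
    topo <- rbind(topo, h$topology)
  }
  atoms <- do.call(rbind, helices)
  atoms$serial <- seq_len(nrow(atoms))
  s <- structure(list(id = id, atoms = atoms), class = "mem_structure")
  if (tilt != 0 || z_offset != 0) {
    s <- transform_structure(s, transform_pose(tilt, 0, z_offset))
  }
  # sample types at the placed depths, then relabel the alanine template
  cen <- scoring_centres(s, quiet = TRUE)
  seqv <- .sample_sequence(spec, cen$z)
  s <- .relabel_residues(s, cen, seqv)
  topo <- topology(topo$chain, topo$start, topo$end, topo$sense)
  list(structure = s, topology = topo)
}

# assign new one-letter identities to the residues listed in `cen`
.relabel_residues <- function(s, cen, seqv) {
  three <- names(.AA_THREE_TO_ONE)[match(seqv, .AA_THREE_TO_ONE)]
  a <- s$atoms
  key <- paste(a$chain, a$res_seq, a$i_code, sep = "\r")
  ckey <- paste(cen$chain, cen$res_seq, cen$i_code, sep = "\r")
  m <- match(key, ckey)
  hit <- !is.na(m) & !a$het
  a$res_name[hit] <- three[m[hit]]
  a <- a[!(a$res_name == "GLY" & a$name == "CB" & !a$het), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  s$atoms <- a
  s
}

#' Sample a synthetic pre-oriented training set
#'
#' Generates `n_structures` multi-helix bundles at the canonical
#' orientation (membrane normal = z, centre z = 0) with residue types
#' drawn from the depth profile, and a manifest carrying the metadata the
#' training routine consumes. Each bundle gets a random native tilt drawn
#' uniformly from `tilt_range`: real pre-oriented structures are centred
#' with the membrane normal along z but their helices are natively
#' tilted, which is also what makes the training depths cover each slice
#' continuously (perfectly vertical ideal helices would put every scoring
#' centre at an exact multiple of the 1.5 A rise, aliasing the depth
#' statistics against the slice grid). Reproducible by seed; when
#' `out_dir` is given the bundles are also written as PDB files and the
#' manifest gains a `path` column.
#'
#' @param spec A `mem_depth_spec`.
#' @param n_structures Number of bundles.
#' @param seed Integer seed.
#' @param n_helices,n_res Bundle geometry.
#' @param tilt_range Range of native bundle tilts, degrees.
#' @param out_dir Optional output directory.
#' @return List with `structures` (list of `mem_structure`), `topologies`,
#'   and `manifest` (data.frame with `id`, `kind`, `resolution`,
#'   `superfamily`, `identity_partners`, and a `structure` list-column).
#' @export
sample_training_set <- function(spec = depth_spec(), n_structures = 183,
                                seed = 1, n_helices = 8, n_res = 51,
                                tilt_range = c(0, 25), out_dir = NULL) {
  stopifnot(n_structures >= 1)
  set.seed(seed)
  structures <- vector("list", n_structures)
  topologies <- vector("list", n_structures)
  ids <- sprintf("syn%03d", seq_len(n_structures))
  for (i in seq_len(n_structures)) {
    b <- build_bundle(spec, n_helices = n_helices, n_res = n_res, id = ids[i],
                      tilt = runif(1, tilt_range[1], tilt_range[2]))
    structures[[i]] <- b$structure
    topologies[[i]] <- b$topology
  }
  manifest <- data.frame(
    id = ids, kind = "alpha", resolution = 2.0,
    superfamily = sprintf("synfam%02d", seq_len(n_structures)),
    identity_partners = "", stringsAsFactors = FALSE)
  manifest$structure <- I(structures)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(out_dir, paste0(ids, ".pdb"))
    for (i in seq_len(n_structures)) {
      write_structure(structures[[i]], file = manifest$path[i])
    }
  }
  list(structures = structures, topologies = topologies, manifest = manifest)
}

#' Build a synthetic decoy ensemble
#'
#' The native model is a bundle sampled from the depth profile; each decoy
#' scrambles a fraction of residue identities (permuting them across
#' randomly chosen positions, destroying the depth-type association while
#' preserving composition and geometry). Model quality is recorded as a
#' pseudo TM-score of `1 - fraction`.
#'
#' @param spec A `mem_depth_spec`.
#' @param n_decoys Number of decoys.
#' @param scramble_fractions Fractions in \[0, 1\], recycled over decoys.
#' @param seed Integer seed.
#' @param n_helices,n_res Bundle geometry.
#' @return List with `models` (native first, id `"native"`), `topology`,
#'   and `info` (data.frame `id`, `fraction`, `tm_score`).
#' @export
make_decoy_ensemble <- function(spec = depth_spec(), n_decoys = 20,
                                scramble_fractions = seq(0.1, 1, by = 0.1),
                                seed = 1, n_helices = 6, n_res = 51) {
  stopifnot(n_decoys >= 2)
  set.seed(seed)
  native <- build_bundle(spec, n_helices = n_helices, n_res = n_res,
                         id = "native")
  fr <- rep_len(scramble_fractions, n_decoys)
  models <- vector("list", n_decoys + 1L)
  models[[1L]] <- native$structure
  for (d in seq_len(n_decoys)) {
    models[[d + 1L]] <- .scramble_identities(native$structure, fr[d],
                                             id = sprintf("decoy%03d", d))
  }
  info <- data.frame(
    id = c("native", sprintf("decoy%03d", seq_len(n_decoys))),
    fraction = c(0, fr), tm_score = c(1, 1 - fr),
    stringsAsFactors = FALSE)
  list(models = models, topology = native$topology, info = info)
}

# permute residue identities across a random fraction of positions
.scramble_identities <- function(s, fraction, id = "decoy") {
  a <- s$atoms
  pol <- !a$het
  key <- paste(a$chain, a$res_seq, a$i_code, sep = "\r")
  res_keys <- unique(key[pol])
  n_pick <- round(fraction * length(res_keys))
  s$id <- id
  if (n_pick < 2L) return(s)
  picked <- sample(res_keys, n_pick)
  names_by_res <- a$res_name[pol][match(picked, key[pol])]
  shuffled <- sample(names_by_res)
  if (identical(shuffled, names_by_res)) {
    # a no-op permutation would make a "decoy" identical to the native;
    # rotate instead so a positive fraction always changes something
    shuffled <- names_by_res[c(seq_len(n_pick)[-1], 1L)]
  }
  for (i in seq_along(picked)) {
    a$res_name[key == picked[i] & pol] <- shuffled[i]
  }
  # glycine carries no C-beta: drop CB of residues that became GLY and
  # synthesise nothing for residues that ceased to be GLY (their centre
  # falls back to CA, which the scoring rules allow)
  a <- a[!(a$res_name == "GLY" & a$name == "CB" & pol), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  s$atoms <- a
  s
}
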