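## structure_io: fixed-width PDB v3.3 reading/writing and scoring centres.

#' Read a PDB-format structure
#'
#' Parses ATOM records into polymer chains and collects HETATM records
#' (lipids, ions, ...) separately. Only MODEL 1 of a multi-model file is
#' used. Alternate locations keep the first-listed conformer (blank or
#' 'A'); others are dropped. MSE and SEC are mapped to MET and CYS;
#' other non-standard polymer residues are skipped with a warning.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param id Structure identifier; defaults to the file basename.
#' @param chains Optional character vector restricting parsing to the
#'   listed chain identifiers.
#' @return An object of class `mem_structure`: a list with elements
#'   `id` (character) and `atoms`, a data.frame with one row per retained
#'   atom and columns `serial`, `name`, `alt_loc`, `res_name`, `chain`,
#'   `res_seq`, `i_code`, `x`, `y`, `z`, `element`, `het`.
#' @export
read_structure <- function(pdb, id = NULL, chains = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(pdb))
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "structure"
  }

  # MODEL 1 only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1L) {
    mend <- grep("^ENDMDL", lines)
    end1 <- if (length(mend)) mend[1] else length(lines)
    lines <- lines[seq_len(end1)]
  }

  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  rec <- rec[keep]
  if (!any(rec == "ATOM  ")) stop("no structure: input contains no ATOM records")

  fx <- function(lo, hi) trimws(substr(lines, lo, hi))
  xs <- suppressWarnings(as.numeric(fx(31, 38)))
  ys <- suppressWarnings(as.numeric(fx(39, 46)))
  zs <- suppressWarnings(as.numeric(fx(47, 54)))
  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(zs)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed coordinates skipped")
  }

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(fx(7, 11))),
    name = fx(13, 16),
    alt_loc = substr(lines, 17, 17),
    res_name = fx(18, 20),
    chain = substr(lines, 22, 22),
    res_seq = suppressWarnings(as.integer(fx(23, 26))),
    i_code = substr(lines, 27, 27),
    x = xs, y = ys, z = zs,
    element = fx(77, 78),
    het = rec == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!bad & !is.na(atoms$res_seq), , drop = FALSE]

  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]

  # alt-loc: first-listed conformer per (chain, res, icode, atom name)
  sel <- atoms$alt_loc %in% c(" ", "A", "")
  alt <- atoms[!sel, , drop = FALSE]
  atoms <- atoms[sel, , drop = FALSE]
  if (nrow(alt)) {
    key_a <- paste(atoms$chain, atoms$res_seq, atoms$i_code, atoms$name, atoms$het)
    key_b <- paste(alt$chain, alt$res_seq, alt$i_code, alt$name, alt$het)
    orphan <- !(key_b %in% key_a) & !duplicated(key_b)
    atoms <- rbind(atoms, alt[orphan, , drop = FALSE])
  }

  # polymer atoms must be standard or mapped-standard residues
  pol <- !atoms$het
  known <- atoms$res_name %in% c(names(.AA_THREE_TO_ONE), names(.AA_NONSTANDARD))
  unk <- pol & !known
  if (any(unk)) {
    warning("skipping non-standard polymer residue(s): ",
            paste(unique(atoms$res_name[unk]), collapse = ", "))
    atoms <- atoms[!unk, , drop = FALSE]
  }
  if (!any(!atoms$het)) stop("no structure: no standard polymer residues")

  # strict residue ordering within each chain
  pol_idx <- which(!atoms$het)
  o <- order(atoms$chain[pol_idx], atoms$res_seq[pol_idx], atoms$i_code[pol_idx])
  atoms <- rbind(atoms[pol_idx[o], , drop = FALSE],
                 atoms[atoms$het, , drop = FALSE])
  rownames(atoms) <- NULL

  structure(list(id = id, atoms = atoms), class = "mem_structure")
}

#' @export
print.mem_structure <- function(x, ...) {
  pol <- x$atoms[!x$atoms$het, ]
  nres <- nrow(unique(pol[, c("chain", "res_seq", "i_code")]))
  cat(sprintf("<mem_structure '%s': %d chain(s), %d residues, %d atoms, %d HETATM>\n",
              x$id, length(unique(pol$chain)), nres, nrow(pol),
              sum(x$atoms$het)))
  invisible(x)
}

#' Extract per-residue scoring centres
#'
#' The scoring centre of a residue is its C-beta atom, or C-alpha for
#' glycine. A non-glycine residue lacking a C-beta falls back to its
#' C-alpha (a message is emitted); residues with neither are skipped.
#'
#' @param s A `mem_structure`.
#' @param quiet Suppress fallback messages.
#' @return Data.frame of class `mem_centres` with columns `aa` (one-letter
#'   code), `chain`, `res_seq`, `i_code`, `x`, `y`, `z`.
#' @export
scoring_centres <- function(s, quiet = FALSE) {
  stopifnot(inherits(s, "mem_structure"))
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  a$aa <- .aa_one(a$res_name)
  a <- a[!is.na(a$aa), , drop = FALSE]
  key <- paste(a$chain, a$res_seq, a$i_code, sep = "\r")

  is_cb <- a$name == "CB"
  is_ca <- a$name == "CA"
  want_cb <- a$aa != "G"
  # primary pick: CB for non-gly, CA for gly
  pick <- (want_cb & is_cb) | (!want_cb & is_ca)
  got <- unique(key[pick])
  # fallback: CA for non-gly residues with no CB
  fb <- want_cb & is_ca & !(key %in% got)
  if (any(fb) && !quiet) {
    message(length(unique(key[fb])), " residue(s) lacking CB scored at CA")
  }
  sel <- a[pick | fb, , drop = FALSE]
  sel <- sel[!duplicated(paste(sel$chain, sel$res_seq, sel$i_code, sep = "\r")), ]
  if (!nrow(sel)) stop("no scoring centres")
  out <- sel[, c("aa", "chain", "res_seq", "i_code", "x", "y", "z")]
  rownames(out) <- NULL
  class(out) <- c("mem_centres", "data.frame")
  out
}

# coordinate matrix + aa index vector, the form the C++ kernel consumes
.centres_matrix <- function(centres) {
  list(coords = cbind(centres$x, centres$y, centres$z),
       aa = .aa_index(centres$aa))
}

#' Write a structure as PDB text under a rigid transform
#'
#' All atom coordinates (ATOM and HETATM) are transformed by `t` using the
#' same convention as [apply_transform()]. Two REMARK lines record the
#' transform and the implied membrane boundaries.
#'
#' @param s A `mem_structure`.
#' @param t A `mem_transform` (default identity).
#' @param file Optional path; when given, text is written there.
#' @param half_thickness Membrane half-thickness recorded in the REMARK
#'   line (A).
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_structure <- function(s, t = transform_pose(0, 0, 0), file = NULL,
                            half_thickness = 15) {
  stopifnot(inherits(s, "mem_structure"))
  a <- s$atoms
  xyz <- apply_transform(cbind(a$x, a$y, a$z), t)
  name4 <- ifelse(nchar(a$name) >= 4, a$name,
                  paste0(" ", formatC(a$name, width = -3)))
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$het, "HETATM", "ATOM"),
                   a$serial, name4,
                   ifelse(a$alt_loc == "", " ", a$alt_loc),
                   a$res_name, ifelse(a$chain == "", " ", a$chain),
                   a$res_seq, ifelse(a$i_code == "", " ", a$i_code),
                   xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
  hdr <- c(sprintf("REMARK MEMEMBED TRANSFORM %.4f %.4f %.4f",
                   t$rot_x, t$rot_y, t$dz),
           sprintf("REMARK MEMEMBED MEMBRANE %.2f %.2f",
                   -half_thickness, half_thickness))
  out <- c(hdr, lines, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Apply a rigid transform to a structure
#'
#' @param s A `mem_structure`.
#' @param t A `mem_transform`.
#' @return A new `mem_structure` with transformed coordinates.
#' @export
transform_structure <- function(s, t) {
  stopifnot(inherits(s, "mem_structure"))
  xyz <- apply_transform(cbind(s$atoms$x, s$atoms$y, s$atoms$z), t)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}
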