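# Multi-specimen landmark arrays and TPS input/output.
#
# The container convention follows the field's standard: a numeric array
# of dimension p x 3 x n (landmarks x coordinates x specimens) whose third
# dimnames hold the specimen identifiers.

#' Construct and validate a landmark array
#'
#' Builds the `p x 3 x n` array (landmarks, xyz coordinates, specimens)
#' used throughout the package.  A `p x 3` matrix is promoted to a
#' single-specimen array.
#'
#' @param coords A numeric `p x 3 x n` array or `p x 3` matrix.
#' @param ids Character vector of `n` unique specimen identifiers; taken
#'   from existing dimnames when omitted.
#' @return A validated `p x 3 x n` array with specimen dimnames.
#' @export
landmark_array <- function(coords, ids = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), ncol(coords), 1L))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    abort_validation("coords must be a p x 3 x n array (landmarks x xyz x specimens)")
  if (!is.numeric(coords) || !all(is.finite(coords)))
    abort_validation("landmark coordinates must all be finite numbers")
  n <- dim(coords)[3L]
  if (n < 1L || dim(coords)[1L] < 1L)
    abort_validation("landmark array must contain at least one landmark and one specimen")
  if (is.null(ids)) ids <- dimnames(coords)[[3L]]
  if (is.null(ids)) ids <- paste0("specimen_", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n)
    abort_validation(sprintf("got %d specimen ids for %d specimens", length(ids), n))
  if (anyDuplicated(ids))
    abort_validation("specimen ids must be unique")
  dimnames(coords) <- list(dimnames(coords)[[1L]], c("x", "y", "z"), ids)
  coords
}

specimen_ids <- function(A) dimnames(A)[[3L]]

# one specimen's configuration as a p x 3 matrix (robust to p == 1)
specimen_matrix <- function(A, i) {
  matrix(A[, , i], ncol = 3L, dimnames = list(dimnames(A)[[1L]], dimnames(A)[[2L]]))
}

check_landmark_array <- function(A, what = "data") {
  if (!is.array(A) || length(dim(A)) != 3L)
    abort_validation(sprintf("%s must be a p x 3 x n landmark array (see landmark_array())", what))
  landmark_array(A)
}

#' Translate structures so a chosen landmark sits at a given origin
#'
#' For every specimen, subtracts the difference between the chosen
#' landmark's coordinates and `origin` from all landmarks, so the chosen
#' landmark lands exactly on `origin` (the point `(0, 0, 0)` by default).
#' A pure translation: all inter-landmark distances are unchanged.  This
#' is the step that pins each structure's articulation point to the origin
#' before rotation.
#'
#' @param A A `p x 3 x n` landmark array (or `p x 3` matrix).
#' @param landmark 1-based index of the landmark to pin (typically the
#'   articulation point).
#' @param origin Length-3 target position; defaults to the origin.
#' @return The translated array, same shape and dimnames as the input.
#' @examples
#' A <- landmark_array(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
#' translate_structure(A, 1)[1, , 1]  # landmark 1 now at (0, 0, 0)
#' @export
translate_structure <- function(A, landmark, origin = c(0, 0, 0)) {
  single <- is.matrix(A)
  A <- landmark_array(A)
  landmark <- check_landmark_index(landmark, dim(A)[1L])
  check_vec3(origin, "origin")
  for (i in seq_len(dim(A)[3L])) {
    shift <- A[landmark, , i] - origin
    A[, , i] <- sweep(specimen_matrix(A, i), 2L, shift, "-")
  }
  if (single) specimen_matrix(A, 1L) else A
}

#' Displace a whole structure by a fixed offset
#'
#' Rigidly translates every landmark of every specimen by `offset`.  Used
#' after rotation to separate two standardized structures that would
#' otherwise overlap at the origin; `anchor` names the landmark (normally
#' the articulation point, sitting at the origin after rotation) whose
#' final position therefore becomes `offset` itself.
#'
#' @inheritParams translate_structure
#' @param anchor 1-based index of the reference landmark.
#' @param offset Length-3 displacement vector.
#' @return The displaced array.
#' @export
offset_structure <- function(A, anchor, offset) {
  single <- is.matrix(A)
  A <- landmark_array(A)
  check_landmark_index(anchor, dim(A)[1L], "anchor")
  check_vec3(offset, "offset")
  for (i in seq_len(dim(A)[3L]))
    A[, , i] <- sweep(specimen_matrix(A, i), 2L, offset, "+")
  if (single) specimen_matrix(A, 1L) else A
}

# ---------------------------------------------------------------------------
# TPS format

#' Read a TPS landmark file
#'
#' Parses the plain-text TPS interchange dialect used for 3D landmark
#' data: per specimen a `LM3=n` line, `n` lines of three whitespace-
#' separated coordinates, and optional `SCALE=`, `IMAGE=` and `ID=` lines.
#' Keywords are case-insensitive; blank lines and CRLF endings are
#' accepted.  When a `SCALE=` line is present its value multiplies that
#' specimen's coordinates.  Two-dimensional records (`LM=`) are rejected.
#'
#' @param path Path to the TPS file.
#' @return A `p x 3 x n` landmark array with specimen ids in file order.
#' @export
read_tps <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("TPS file not found: %s", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  specimens <- list()
  ids <- character()
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^lm=", tolower(ln)))
      abort_format("2D TPS records (LM=) are not supported; this package requires 3D (LM3=) data")
    m <- regmatches(ln, regexec("^[Ll][Mm]3=\\s*([0-9]+)\\s*$", ln))[[1L]]
    if (length(m) == 0L)
      abort_format(sprintf("expected an LM3= record at line %d of %s", i, path))
    block <- block + 1L
    nlm <- as.integer(m[2L])
    if (nlm < 1L)
      abort_format(sprintf("specimen block %d declares LM3=0", block))
    if (i + nlm > length(lines))
      abort_format(sprintf("specimen block %d: file ends before %d coordinate lines", block, nlm))
    coord_lines <- lines[(i + 1L):(i + nlm)]
    xyz <- lapply(coord_lines, function(s) {
      vals <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1L]]))
      if (length(vals) != 3L || anyNA(vals))
        abort_format(sprintf("specimen block %d: malformed coordinate line '%s'", block, s))
      vals
    })
    mat <- do.call(rbind, xyz)
    i <- i + nlm + 1L

    id <- NA_character_
    scale <- NA_real_
    while (i <= length(lines) && !grepl("^lm", tolower(lines[i]))) {
      kv <- lines[i]
      low <- tolower(kv)
      if (grepl("^id=", low)) {
        id <- sub("^[Ii][Dd]=", "", kv)
      } else if (grepl("^scale=", low)) {
        scale <- suppressWarnings(as.numeric(sub("^[Ss][Cc][Aa][Ll][Ee]=", "", kv)))
        if (is.na(scale))
          abort_format(sprintf("specimen block %d: malformed SCALE line '%s'", block, kv))
      } else if (grepl("^image=", low)) {
        # ignored: image provenance carries no coordinate information
      } else {
        abort_format(sprintf("unrecognized line '%s' in specimen block %d", kv, block))
      }
      i <- i + 1L
    }
    if (!is.na(scale)) mat <- mat * scale
    if (is.na(id)) {
      id <- paste0("specimen_", block)
      warn_artirot(sprintf("specimen block %d has no ID= line; labelled '%s'", block, id),
                   "artirot_missing_id")
    }
    specimens[[block]] <- mat
    ids[block] <- id
  }
  if (block == 0L)
    abort_format(sprintf("no landmark records found in %s", path))
  counts <- vapply(specimens, nrow, integer(1L))
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1L])[1L]
    abort_format(sprintf(
      "inconsistent landmark counts: specimen '%s' has %d landmarks, expected %d",
      ids[bad], counts[bad], counts[1L]))
  }
  out <- array(NA_real_, dim = c(counts[1L], 3L, block))
  for (k in seq_len(block)) out[, , k] <- specimens[[k]]
  landmark_array(out, ids)
}

#' Write a landmark array to a TPS file
#'
#' Emits one block per specimen: an `LM3=` line, one coordinate line per
#' landmark at full double precision (17 significant digits, so a read
#' back reproduces the values bit-exactly), and an `ID=` line.  No
#' `SCALE=` line is written: coordinates are emitted in their final units.
#' Output is byte-stable across runs for identical input.
#'
#' @param A A `p x 3 x n` landmark array (a joined dataset is fine).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_tps <- function(A, path) {
  A <- check_landmark_array(A)
  ids <- specimen_ids(A)
  p <- dim(A)[1L]
  blocks <- character()
  for (i in seq_len(dim(A)[3L])) {
    coords <- apply(specimen_matrix(A, i), 1L, function(v)
      paste(sprintf("%.17g", v), collapse = " "))
    blocks <- c(blocks, sprintf("LM3=%d", p), coords, sprintf("ID=%s", ids[i]))
  }
  ok <- tryCatch({ writeLines(blocks, path); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    abort_io(sprintf("cannot write TPS file: %s", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Matching and joining

#' Match two landmark datasets by specimen identifier
#'
#' Restricts both arrays to the specimens present in each (by id, so the
#' order of specimens in the two inputs is irrelevant) and reorders both
#' to the first dataset's id order.  Specimens found in only one input are
#' dropped with a warning naming them -- never silently reordered or
#' recycled.
#'
#' @param d1,d2 Landmark arrays (`p x 3 x n`), possibly with different
#'   landmark counts and different specimen sets.
#' @return A list with elements `matched1` and `matched2`, both restricted
#'   to the shared specimens in `d1`'s order.
#' @export
match_datasets <- function(d1, d2) {
  d1 <- check_landmark_array(d1, "d1")
  d2 <- check_landmark_array(d2, "d2")
  ids1 <- specimen_ids(d1)
  ids2 <- specimen_ids(d2)
  keep <- ids1[ids1 %in% ids2]
  if (length(keep) == 0L)
    abort_match("no specimen ids shared between the two datasets; nothing to match")
  dropped <- c(setdiff(ids1, keep), setdiff(ids2, keep))
  if (length(dropped) > 0L)
    warn_artirot(sprintf("dropping unmatched specimens: %s",
                         paste(dropped, collapse = ", ")),
                 "artirot_dropped_specimens")
  list(matched1 = d1[, , keep, drop = FALSE],
       matched2 = d2[, , keep, drop = FALSE])
}

#' Join two landmark arrays along the landmark dimension
#'
#' Concatenates structure 1's landmarks followed by structure 2's for each
#' specimen, producing the joined configuration handed on to downstream
#' shape analysis.  Both inputs must already carry identical specimen ids
#' in identical order (run [match_datasets()] first).  The result carries
#' a per-landmark `provenance` attribute (`"structure1"` / `"structure2"`)
#' so the two structures can be recovered with [split_joined()].
#'
#' @param d1,d2 Landmark arrays with identical specimen ids in identical
#'   order.
#' @return A `(p1 + p2) x 3 x n` landmark array with a `provenance`
#'   attribute.
#' @export
join_arrays <- function(d1, d2) {
  d1 <- check_landmark_array(d1, "d1")
  d2 <- check_landmark_array(d2, "d2")
  ids1 <- specimen_ids(d1)
  ids2 <- specimen_ids(d2)
  if (!identical(ids1, ids2))
    abort_match("specimen ids differ or are ordered differently; run match_datasets() first")
  p1 <- dim(d1)[1L]; p2 <- dim(d2)[1L]
  out <- array(NA_real_, dim = c(p1 + p2, 3L, length(ids1)),
               dimnames = list(NULL, c("x", "y", "z"), ids1))
  out[seq_len(p1), , ] <- d1
  out[p1 + seq_len(p2), , ] <- d2
  attr(out, "provenance") <- rep(c("structure1", "structure2"), c(p1, p2))
  out
}

#' Split a joined dataset back into its two structures
#'
#' Inverse of [join_arrays()]: uses the `provenance` attribute to slice
#' the joined array back into the original structure-1 and structure-2
#' arrays.
#'
#' @param joined A joined landmark array produced by [join_arrays()] (or
#'   by the rotation procedures).
#' @return A list with elements `structure1` and `structure2`.
#' @export
split_joined <- function(joined) {
  prov <- attr(joined, "provenance")
  joined <- check_landmark_array(joined, "joined")
  if (is.null(prov) || length(prov) != dim(joined)[1L])
    abort_validation("no per-landmark provenance attribute; not a joined dataset")
  list(structure1 = joined[prov == "structure1", , , drop = FALSE],
       structure2 = joined[prov == "structure2", , , drop = FALSE])
}
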