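# Standardization of articulated two-structure landmark configurations.
#
# Both procedures place structure 1's articulation axis along (1, 0, 0)
# with its orientation landmark in the xy-plane at positive y, and place
# structure 2's axis at the requested angle within the xy-plane.  Every
# motion applied is a proper rigid motion: shape is untouched, reflections
# are never introduced.

#' Specify the role landmarks and target angle of an articulation
#'
#' Records which landmarks play the geometric roles in the standardization
#' and the target inter-structure angle.  Per structure, the roles are:
#' 1. the articulation (base) landmark, translated to the origin;
#' 2. the axis (end) landmark, defining the structure's main axis;
#' 3. the orientation landmark, fixing the spin about that axis (and with
#'    it the mirroring orientation);
#' 4. (double-point articulations only) a chirality landmark off the plane
#'    of the first three, used to detect reflected (mirror-digitized)
#'    specimens.
#'
#' @param roles1,roles2 Integer vectors of 1-based landmark indices:
#'   length 3 for a single-point articulation, 4 for a double-point one.
#'   Indices must be distinct within a structure.
#' @param angle Target angle between the two structures' axes, in degrees
#'   (0 to 360).
#' @return An object of class `"articulation_spec"`.
#' @export
articulation_spec <- function(roles1, roles2, angle) {
  check_roles <- function(r, what) {
    if (!is.numeric(r) || !(length(r) %in% c(3L, 4L)) || any(r != round(r)))
      abort_validation(sprintf("%s must be 3 or 4 whole landmark indices", what))
    if (anyDuplicated(r))
      abort_validation(sprintf("%s must be distinct landmark indices", what))
    as.integer(r)
  }
  roles1 <- check_roles(roles1, "roles1")
  roles2 <- check_roles(roles2, "roles2")
  if (length(roles1) != length(roles2))
    abort_validation("roles1 and roles2 must both name 3 (single) or 4 (double) landmarks")
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle) ||
      angle < 0 || angle > 360)
    abort_validation("angle must be a single number between 0 and 360 degrees")
  structure(list(roles1 = roles1, roles2 = roles2, angle = angle,
                 type = if (length(roles1) == 3L) "single" else "double"),
            class = "articulation_spec")
}

check_roles_in_range <- function(roles, p, what) {
  if (any(roles < 1L | roles > p))
    abort_index(sprintf("%s contains landmark indices outside [1, %d]", what, p))
  roles
}

# signed volume of the tetrahedron spanned by rows (i1..i4) of a config;
# its sign encodes handedness and is invariant under proper rigid motion
signed_volume <- function(m, idx) {
  det(rbind(m[idx[2L], ] - m[idx[1L], ],
            m[idx[3L], ] - m[idx[1L], ],
            m[idx[4L], ] - m[idx[1L], ]))
}

# Align one structure's configuration (base landmark already at the
# origin) so its base->end axis lies along (1,0,0) and the orientation
# landmark sits in the xy-plane at positive y.
standardize_config <- function(m, base, end, orient, specimen = "?", structure = "?") {
  context <- sprintf(" (specimen '%s', structure %s)", specimen, structure)
  axis_vec <- m[end, ] - m[base, ]
  scale <- max(apply(m, 2L, function(v) diff(range(v))), 1e-12)
  if (vec_norm(axis_vec) < 1e-9 * scale)
    abort_degenerate(paste0("axis landmarks coincide; rotation axis undefined", context))
  m <- rotate_points(m, align_rotation(axis_vec, c(1, 0, 0)))
  tryCatch(
    in_axis_correction(m, orient, c(1, 0, 0), direction = c(0, 1, 0)),
    artirot_degenerate = function(e)
      abort_degenerate(paste0("orientation landmark lies on the articulation axis", context)))
}

#' Measure the angle between the two structures' articulation axes
#'
#' For each specimen, the angle (in degrees, in `[0, 180]`) between the
#' base-to-end axis vectors of the two structures.  After standardization
#' this equals the requested target angle (its reflex complement for
#' targets above 180 degrees, since an unsigned angle cannot exceed 180).
#'
#' @param d1,d2 Landmark arrays with identical specimen ids.
#' @param base1,end1 1-based indices of structure 1's articulation and
#'   axis landmarks.
#' @param base2,end2 Likewise for structure 2.
#' @return Named numeric vector of per-specimen angles in degrees.
#' @export
inter_axis_angle <- function(d1, d2, base1, end1, base2, end2) {
  d1 <- check_landmark_array(d1, "d1")
  d2 <- check_landmark_array(d2, "d2")
  if (!identical(specimen_ids(d1), specimen_ids(d2)))
    abort_match("specimen ids differ; run match_datasets() first")
  base1 <- check_landmark_index(base1, dim(d1)[1L], "base1")
  end1  <- check_landmark_index(end1,  dim(d1)[1L], "end1")
  base2 <- check_landmark_index(base2, dim(d2)[1L], "base2")
  end2  <- check_landmark_index(end2,  dim(d2)[1L], "end2")
  n <- dim(d1)[3L]
  out <- vapply(seq_len(n), function(i) {
    a1 <- d1[end1, , i] - d1[base1, , i]
    a2 <- d2[end2, , i] - d2[base2, , i]
    if (vec_norm(a1) == 0 || vec_norm(a2) == 0)
      abort_degenerate(sprintf("axis undefined for specimen '%s'", specimen_ids(d1)[i]))
    # atan2 form of the inter-vector angle: equal to acos(u.v/(|u||v|))
    # but numerically stable for near-parallel axes
    atan2(vec_norm(cross3(a1, a2)), sum(a1 * a2)) * 180 / pi
  }, numeric(1L))
  names(out) <- specimen_ids(d1)
  out
}

#' Screen role landmarks for numerically fragile choices
#'
#' Flags, per specimen and structure, role-landmark choices that make the
#' standardization ill-conditioned: an axis pair closer than `1e-6` times
#' the structure's centroid size (rotation axis undefined), or an
#' axis-plus-orientation triple whose angle at the axis has sine below
#' `0.01` (spin correction unstable).  The report warns; it never blocks
#' execution.  As guidance for landmark choice, the report also carries an
#' informational per-specimen matrix of how far the orientation landmark
#' is from sharing a coordinate with the axis landmark (attribute
#' `shared_coordinate_deviation`); this is advice, not a flag.
#'
#' @param d1,d2 Landmark arrays with identical specimen ids.
#' @param spec An [articulation_spec()].
#' @param warn Emit a summary warning when anything is flagged
#'   (default `TRUE`).
#' @return A data frame with columns `specimen`, `structure`, `flag`,
#'   `value`; zero rows when nothing is flagged.
#' @export
check_landmark_quality <- function(d1, d2, spec, warn = TRUE) {
  d1 <- check_landmark_array(d1, "d1")
  d2 <- check_landmark_array(d2, "d2")
  if (!inherits(spec, "articulation_spec"))
    abort_validation("spec must be an articulation_spec()")
  check_roles_in_range(spec$roles1, dim(d1)[1L], "roles1")
  check_roles_in_range(spec$roles2, dim(d2)[1L], "roles2")

  rows <- list()
  dev <- matrix(NA_real_, nrow = dim(d1)[3L], ncol = 2L,
                dimnames = list(specimen_ids(d1), c("structure1", "structure2")))
  for (s in 1:2) {
    d <- if (s == 1L) d1 else d2
    roles <- if (s == 1L) spec$roles1 else spec$roles2
    for (i in seq_len(dim(d)[3L])) {
      m <- specimen_matrix(d, i)
      id <- specimen_ids(d)[i]
      centroid_size <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
      axis_len <- vec_norm(m[roles[2L], ] - m[roles[1L], ])
      if (axis_len < 1e-6 * centroid_size) {
        rows[[length(rows) + 1L]] <- data.frame(
          specimen = id, structure = s, flag = "coincident_axis_pair",
          value = axis_len)
      } else {
        u <- m[roles[2L], ] - m[roles[1L], ]
        v <- m[roles[3L], ] - m[roles[1L], ]
        sin_at_axis <- if (vec_norm(v) == 0) 0 else
          vec_norm(cross3(u, v)) / (vec_norm(u) * vec_norm(v))
        if (sin_at_axis < 0.01)
          rows[[length(rows) + 1L]] <- data.frame(
            specimen = id, structure = s, flag = "collinear_roles",
            value = sin_at_axis)
      }
      dev[i, s] <- min(abs(m[roles[3L], ] - m[roles[2L], ]))
    }
  }
  report <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(specimen = character(), structure = integer(),
               flag = character(), value = numeric())
  attr(report, "shared_coordinate_deviation") <- dev
  if (warn && nrow(report) > 0L)
    warn_artirot(sprintf(
      "role landmarks are not optimal for %d specimen/structure case(s): %s",
      nrow(report),
      paste(unique(sprintf("%s/structure%d [%s]", report$specimen,
                           report$structure, report$flag)), collapse = "; ")),
      "artirot_quality")
  report
}

# shared machinery for both rotation procedures.  Returns the two rotated
# arrays (structure 2 already placed at the target angle).
rotate_pair <- function(data.1, data.2, spec, check_reflection) {
  matched <- match_datasets(data.1, data.2)
  d1 <- matched$matched1
  d2 <- matched$matched2
  check_roles_in_range(spec$roles1, dim(d1)[1L], "roles1")
  check_roles_in_range(spec$roles2, dim(d2)[1L], "roles2")
  check_landmark_quality(d1, d2, spec)

  # pin each structure's articulation landmark to the origin (idempotent
  # if the caller already translated)
  d1 <- translate_structure(d1, spec$roles1[1L])
  d2 <- translate_structure(d2, spec$roles2[1L])

  ids <- specimen_ids(d1)
  place2 <- rotation_matrix(c(0, 0, 1), spec$angle * pi / 180)
  for (i in seq_along(ids)) {
    m1 <- standardize_config(specimen_matrix(d1, i), spec$roles1[1L],
                             spec$roles1[2L], spec$roles1[3L], ids[i], "1")
    m2 <- standardize_config(specimen_matrix(d2, i), spec$roles2[1L],
                             spec$roles2[2L], spec$roles2[3L], ids[i], "2")
    d1[, , i] <- m1
    d2[, , i] <- rotate_points(m2, place2)   # swing axis 2 to the target angle
  }

  if (check_reflection) {
    for (s in 1:2) {
      d <- if (s == 1L) d1 else d2
      roles <- if (s == 1L) spec$roles1 else spec$roles2
      vols <- vapply(seq_along(ids), function(i)
        signed_volume(specimen_matrix(d, i), roles), numeric(1L))
      signs <- sign(vols)
      if (any(signs == 0))
        abort_degenerate(sprintf(
          "chirality landmark coplanar with the other roles (structure %d, specimen '%s')",
          s, ids[which(signs == 0)[1L]]))
      if (length(unique(signs)) > 1L) {
        majority <- if (sum(signs > 0) >= sum(signs < 0)) 1 else -1
        minority <- ids[signs != majority]
        abort_reflection(sprintf(
          paste0("structure %d appears reflected (mirror-digitized) in specimen(s) %s: ",
                 "the role-landmark handedness disagrees with the other specimens; ",
                 "a rigid rotation cannot undo a reflection"),
          s, paste(sQuote(minority), collapse = ", ")))
      }
    }
  }
  list(rotated1 = d1, rotated2 = d2)
}

#' Standardize a single-point articulation
#'
#' Rigidly rotates two structures that share one articulation point (for
#' example a humerus and radioulna meeting at the elbow) into a
#' standardized relative pose.  For every specimen shared by the two
#' datasets: structure 1 is translated so landmark `land.a` sits at the
#' origin, rotated so its `land.a`-to-`land.b` axis lies along `(1,0,0)`,
#' and spun about that axis until landmark `land.c` lies in the xy-plane
#' at positive y (which also resolves the mirroring ambiguity); structure
#' 2 is treated the same way using `land.d`, `land.e`, `land.f`, and then
#' swung within the xy-plane so its axis forms `angle` degrees with
#' structure 1's (i.e. along [vector_from_angle()] of `angle`).  All
#' motions are rigid: per-structure shape is untouched.
#'
#' Specimens present in only one dataset are dropped with a warning.
#' Ill-chosen role landmarks trigger a quality warning (see
#' [check_landmark_quality()]); degenerate ones (coincident axis pair,
#' orientation landmark on the axis) raise an error naming the specimen.
#'
#' @param data.1,data.2 Landmark arrays (`p x 3 x n`) for the two
#'   structures, specimen ids in the third dimnames.  They need not be
#'   pre-translated; translation to the origin is applied (again) anyway.
#' @param land.a,land.b,land.c 1-based indices of structure 1's
#'   articulation, axis and orientation landmarks.
#' @param land.d,land.e,land.f Likewise for structure 2.
#' @param angle Target angle between the two structures, in degrees
#'   (0-360).
#' @return A joined landmark array (structure 1's landmarks first) with a
#'   `provenance` attribute; see [join_arrays()].
#' @examples
#' pair <- make_articulated_pair(n_specimens = 3, seed = 7)
#' joined <- simple_rotation(pair$structure1, pair$structure2,
#'                           land.a = 1, land.b = 2, land.c = 3,
#'                           land.d = 1, land.e = 2, land.f = 3, angle = 90)
#' @export
simple_rotation <- function(data.1, data.2, land.a, land.b, land.c,
                            land.d, land.e, land.f, angle) {
  spec <- articulation_spec(c(land.a, land.b, land.c),
                            c(land.d, land.e, land.f), angle)
  rot <- rotate_pair(data.1, data.2, spec, check_reflection = FALSE)
  join_arrays(rot$rotated1, rot$rotated2)
}

#' Standardize a double-point articulation
#'
#' Standardizes two detached structures articulating at two hinge points
#' (for example a skull and mandible meeting at the two jaw joints).
#' Each structure requires four role landmarks: the two hinge landmarks
#' defining its articulation axis, an orientation landmark removing the
#' torsional spin about that axis, and a chirality landmark off the plane
#' of the other three.  Per structure, both are translated to the origin
#' (the structures are not attached, so both share the origin), the hinge
#' axis is aligned with `(1,0,0)`, the torsion is removed by spinning the
#' orientation landmark into the xy-plane at positive y, and the
#' chirality landmark's handedness is checked across specimens -- a
#' specimen whose role-landmark handedness disagrees with the rest has
#' been digitized mirrored, which no rigid rotation can repair, and
#' raises an error rather than being silently "fixed".  Structure 2 is
#' finally swung within the xy-plane to the target angle.
#'
#' Unlike [simple_rotation()], the two rotated structures are returned
#' separately (join them with [join_arrays()], optionally after
#' [offset_structure()] to keep them from overlapping at the origin).
#'
#' @inheritParams simple_rotation
#' @param land.a,land.b,land.c,land.d Structure 1's hinge pair,
#'   orientation and chirality landmarks (1-based).
#' @param land.e,land.f,land.g,land.h Likewise for structure 2.
#' @return A list with elements `rotated1` and `rotated2`, the two
#'   standardized landmark arrays on the matched specimen set.
#' @examples
#' pair <- make_articulated_pair(n_specimens = 3, joint_type = "double", seed = 7)
#' rot <- double_rotation(pair$structure1, pair$structure2,
#'                        land.a = 1, land.b = 2, land.c = 3, land.d = 4,
#'                        land.e = 1, land.f = 2, land.g = 3, land.h = 4,
#'                        angle = 45)
#' joined <- join_arrays(rot$rotated1, rot$rotated2)
#' @export
double_rotation <- function(data.1, data.2, land.a, land.b, land.c, land.d,
                            land.e, land.f, land.g, land.h, angle) {
  spec <- articulation_spec(c(land.a, land.b, land.c, land.d),
                            c(land.e, land.f, land.g, land.h), angle)
  rotate_pair(data.1, data.2, spec, check_reflection = TRUE)
}

#' Resolve the mirrored placement of an axis-aligned structure
#'
#' Spins an already axis-aligned configuration about `axis` so that the
#' orientation landmark's out-of-plane coordinate is zero and its
#' in-plane coordinate strictly positive, i.e. the structure sits on the
#' canonical side of the reference plane instead of the mirrored one.
#' Implemented as an in-axis rotation (see [in_axis_correction()]):
#' handedness is never altered.
#'
#' @param points A `p x 3` matrix, main axis already along `axis`.
#' @param axis Unit rotation axis.
#' @param orient 1-based index of the orientation landmark (must be off
#'   the axis).
#' @return The rotated `p x 3` matrix.
#' @export
mirror_correct <- function(points, axis, orient) {
  in_axis_correction(points, orient, axis)
}
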