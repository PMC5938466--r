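# Synthetic articulated specimens with known ground truth.
#
# One fixed template shape per structure, already in standardized pose
# (role landmarks 1..3/4: articulation point at the origin, axis landmark
# on (1,0,0), orientation landmark in the xy-plane at positive y,
# chirality landmark above the plane).  Each simulated specimen is that
# template under a recorded random joint angle and an independent random
# proper rigid motion per structure -- exactly the nuisance variation the
# standardization procedures are meant to remove.

# restore the caller's RNG state on exit
local_seed <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  if (has_seed) {
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() rm(".Random.seed", envir = globalenv())
  }
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- vec_norm(v)
    if (n > 1e-6) return(v / n)
  }
}

# uniform random proper rotation via a random axis and angle, built with
# the package's own axis-angle primitive (independently cross-checked
# against a quaternion construction in the test suite)
random_rotation <- function() {
  rotation_matrix(random_unit_vector(), stats::runif(1L, 0, 2 * pi))
}

# a bone-like template: role landmarks at prescribed, well-conditioned
# positions, remaining landmarks scattered along the axis
make_template <- function(n_landmarks, axis_length, joint_type) {
  n_roles <- if (joint_type == "double") 4L else 3L
  roles <- rbind(
    c(0, 0, 0),                                   # articulation / hinge 1
    c(axis_length, 0, 0),                         # axis end / hinge 2
    c(0.45 * axis_length, 0.4 * axis_length, 0),  # orientation
    c(0.6 * axis_length, 0.15 * axis_length, 0.35 * axis_length))[seq_len(n_roles), , drop = FALSE]
  extra <- n_landmarks - n_roles
  body <- cbind(stats::runif(extra, -0.1 * axis_length, 1.1 * axis_length),
                stats::runif(extra, -0.4 * axis_length, 0.4 * axis_length),
                stats::runif(extra, -0.4 * axis_length, 0.4 * axis_length))
  rbind(roles, body)
}

#' Generate a synthetic articulated two-structure specimen set
#'
#' Emulates landmark data digitized on an articulated pair of structures
#' (humerus/radioulna-like for `joint_type = "single"`,
#' skull/mandible-like for `"double"`): every specimen is the same
#' underlying pair of template shapes, posed at a random joint angle and
#' then subjected to an independent random proper rotation and
#' translation per structure, as happens when specimens are scanned in
#' arbitrary orientations with freely moving joints.  Optional isotropic
#' Gaussian noise is added to the non-role landmarks only, so the role
#' geometry stays non-degenerate by construction.
#'
#' The role landmarks occupy the first 3 (single) or 4 (double) positions
#' of each structure: articulation point, axis end, orientation landmark,
#' and (double only) chirality landmark.  All applied transforms are
#' recorded, making pose-invariance fully checkable: standardizing any
#' specimen must reproduce the standardized template.
#'
#' @param n_specimens Number of simulated specimens.
#' @param n_landmarks Length-2 integer vector: landmarks per structure
#'   (at least 4 each).
#' @param joint_type `"single"` (one shared articulation point, 3 role
#'   landmarks) or `"double"` (two-hinge articulation, 4 role landmarks).
#' @param angle_range_deg Length-2 range, in degrees within `[0, 360]`,
#'   from which each specimen's joint angle is drawn uniformly.
#' @param noise_sd Standard deviation of coordinate noise on non-role
#'   landmarks (same length units as the templates, whose axes are about
#'   2 units long); 0 for exactly rigid specimens.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return An object of class `"synthetic_pair"`: a list with the two
#'   landmark arrays (`structure1`, `structure2`), the templates
#'   (`template1`, `template2`), role indices (`roles1`, `roles2`), the
#'   per-specimen `joint_angles_deg`, and the applied `rotations` and
#'   `translations` per structure.
#' @export
make_articulated_pair <- function(n_specimens = 10,
                                  n_landmarks = c(12, 15),
                                  joint_type = c("single", "double"),
                                  angle_range_deg = c(20, 160),
                                  noise_sd = 0,
                                  seed = 1) {
  joint_type <- match.arg(joint_type)
  if (length(n_landmarks) != 2L || any(n_landmarks < 4L))
    abort_validation("n_landmarks must give at least 4 landmarks per structure")
  if (length(angle_range_deg) != 2L || any(angle_range_deg < 0) ||
      any(angle_range_deg > 360) || angle_range_deg[1L] > angle_range_deg[2L])
    abort_validation("angle_range_deg must be an increasing range within [0, 360]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_validation("noise_sd must be non-negative")
  if (n_specimens < 1L)
    abort_validation("n_specimens must be at least 1")

  restore <- local_seed(as.integer(seed))
  on.exit(restore())

  n_roles <- if (joint_type == "double") 4L else 3L
  template1 <- make_template(n_landmarks[1L], axis_length = 2.0, joint_type)
  template2 <- make_template(n_landmarks[2L], axis_length = 2.6, joint_type)
  ids <- sprintf("spec_%02d", seq_len(n_specimens))

  arr1 <- array(NA_real_, dim = c(n_landmarks[1L], 3L, n_specimens))
  arr2 <- array(NA_real_, dim = c(n_landmarks[2L], 3L, n_specimens))
  joint_angles <- numeric(n_specimens)
  rot1 <- rot2 <- vector("list", n_specimens)
  tra1 <- tra2 <- vector("list", n_specimens)

  for (i in seq_len(n_specimens)) {
    joint_angles[i] <- stats::runif(1L, angle_range_deg[1L], angle_range_deg[2L])
    # pose structure 2 at the joint angle within the articulation plane
    pose2 <- rotate_points(template2,
                           rotation_matrix(c(0, 0, 1), joint_angles[i] * pi / 180))
    m1 <- template1
    m2 <- pose2
    if (noise_sd > 0) {
      free1 <- (n_roles + 1L):n_landmarks[1L]
      free2 <- (n_roles + 1L):n_landmarks[2L]
      m1[free1, ] <- m1[free1, ] + stats::rnorm(length(free1) * 3L, sd = noise_sd)
      m2[free2, ] <- m2[free2, ] + stats::rnorm(length(free2) * 3L, sd = noise_sd)
    }
    rot1[[i]] <- random_rotation(); tra1[[i]] <- stats::runif(3L, -5, 5)
    rot2[[i]] <- random_rotation(); tra2[[i]] <- stats::runif(3L, -5, 5)
    arr1[, , i] <- sweep(rotate_points(m1, rot1[[i]]), 2L, tra1[[i]], "+")
    arr2[, , i] <- sweep(rotate_points(m2, rot2[[i]]), 2L, tra2[[i]], "+")
  }

  structure(list(
    structure1 = landmark_array(arr1, ids),
    structure2 = landmark_array(arr2, ids),
    template1 = template1,
    template2 = template2,
    roles1 = seq_len(n_roles),
    roles2 = seq_len(n_roles),
    joint_type = joint_type,
    joint_angles_deg = stats::setNames(joint_angles, ids),
    rotations = list(structure1 = rot1, structure2 = rot2),
    translations = list(structure1 = tra1, structure2 = tra2),
    noise_sd = noise_sd,
    seed = as.integer(seed)),
    class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "Synthetic articulated pair: %d specimens, %s-point joint,\n  %d + %d landmarks, joint angles %.1f-%.1f deg, noise sd %g, seed %d\n",
    dim(x$structure1)[3L], x$joint_type, dim(x$structure1)[1L],
    dim(x$structure2)[1L], min(x$joint_angles_deg), max(x$joint_angles_deg),
    x$noise_sd, x$seed))
  invisible(x)
}

#' Generate deliberately degenerate articulated fixtures
#'
#' Produces labelled structure pairs that each trigger exactly one
#' documented warning or error path of the standardization procedures:
#'
#' * `collinear`: structure 1's orientation landmark lies on its
#'   articulation axis in every specimen, so [check_landmark_quality()]
#'   flags a collinear role triple (and rotation raises a
#'   degenerate-geometry error).
#' * `coincident`: structure 1's two axis landmarks coincide, so the
#'   rotation axis is undefined.
#' * `reflected`: one specimen of structure 1 is mirrored (z negated),
#'   so [double_rotation()] raises a reflection error.
#' * `orient_on_axis`: as `collinear`, but only the spin-correction
#'   degeneracy is present (orientation landmark exactly on the axis,
#'   axis pair fine).
#'
#' @param seed Integer seed for the underlying clean specimen sets.
#' @return A named list; each element is a list with `structure1`,
#'   `structure2` and the [articulation_spec()] to use.
#' @export
make_degenerate_cases <- function(seed = 1) {
  base_single <- make_articulated_pair(n_specimens = 3, joint_type = "single",
                                       seed = seed)
  base_double <- make_articulated_pair(
    n_specimens = 3, joint_type = "double",
    seed = as.integer((as.numeric(seed) + 1) %% .Machine$integer.max))
  spec3 <- articulation_spec(1:3, 1:3, 90)
  spec4 <- articulation_spec(1:4, 1:4, 45)

  collinear <- base_single
  for (i in seq_len(dim(collinear$structure1)[3L])) {
    m <- specimen_matrix(collinear$structure1, i)
    # orientation landmark moved onto the articulation axis
    m[3L, ] <- m[1L, ] + 0.5 * (m[2L, ] - m[1L, ])
    collinear$structure1[, , i] <- m
  }

  coincident <- base_single
  for (i in seq_len(dim(coincident$structure1)[3L]))
    coincident$structure1[2L, , i] <- coincident$structure1[1L, , i]

  reflected <- base_double
  m <- specimen_matrix(reflected$structure1, 2L)
  m[, 3L] <- -m[, 3L]                       # mirror one specimen only
  reflected$structure1[, , 2L] <- m

  list(
    collinear = list(structure1 = collinear$structure1,
                     structure2 = collinear$structure2, spec = spec3),
    coincident = list(structure1 = coincident$structure1,
                      structure2 = coincident$structure2, spec = spec3),
    reflected = list(structure1 = reflected$structure1,
                     structure2 = reflected$structure2, spec = spec4),
    orient_on_axis = list(structure1 = collinear$structure1,
                          structure2 = collinear$structure2, spec = spec3))
}
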