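#' Apply a rigid transform to a structure model
#'
#' @param model A [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed [structure_model()].
#' @export
apply_transform <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z)
  new <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  atoms <- model$atoms
  atoms$x <- new[, 1]; atoms$y <- new[, 2]; atoms$z <- new[, 3]
  structure_model(atoms, model$domains)
}

# Kabsch: least-squares rotation+translation carrying `from` onto `to`
# (n x 3 matrices, matched rows). Returns list(rotation, translation, rmsd).
kabsch <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), nrow(from) >= 3)
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  sv <- svd(t(A) %*% B)
  # guard against degenerate (collinear) point sets: rank < 2
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cf)
  moved <- sweep(from %*% t(R), 2, -tr)
  rmsd <- sqrt(mean(rowSums((moved - to)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Superpose two models through a shared domain
#'
#' Least-squares (Kabsch) superposition of the mobile model onto the
#' reference using the C-alpha atoms of a shared domain, matched by
#' author residue number. This is the elementary step for assembling a
#' composite filament model from overlapping fragment structures.
#'
#' @param mobile,reference [structure_model()]s that both contain a
#'   domain labelled `selection`.
#' @param selection Domain label used for matching.
#' @return A list with `rotation` (3x3), `translation` (length 3),
#'   `rmsd` (Angstrom, over the matched set), `n_matched`, and
#'   `transformed` (the whole mobile model moved by the transform).
#' @export
superpose_shared_domain <- function(mobile, reference, selection) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  am <- domain_atoms(mobile, selection)
  ar <- domain_atoms(reference, selection)
  common <- intersect(am$resno, ar$resno)
  if (length(common) < 3) {
    stop("need at least 3 shared C-alpha positions in domain '", selection,
         "' (found ", length(common), ")")
  }
  am <- am[match(common, am$resno), ]
  ar <- ar[match(common, ar$resno), ]
  k <- kabsch(cbind(am$x, am$y, am$z), cbind(ar$x, ar$y, ar$z))
  list(
    rotation = k$rotation,
    translation = k$translation,
    rmsd = k$rmsd,
    n_matched = length(common),
    transformed = apply_transform(mobile, k$rotation, k$translation)
  )
}

#' Merge structure models into one composite model
#'
#' Concatenates atoms and domain tables; domains whose labels already
#' exist in an earlier model are dropped (the earlier copy wins), which
#' is the usual situation when fragments overlap in a shared domain.
#'
#' @param ... [structure_model()]s, already placed in a common frame.
#' @return A [structure_model()].
#' @export
merge_models <- function(...) {
  models <- list(...)
  stopifnot(length(models) >= 1)
  atoms <- list(); domains <- list(); seen <- character(0)
  for (m in models) {
    stopifnot(inherits(m, "structure_model"))
    keep <- !(m$domains$label %in% seen)
    d <- m$domains[keep, ]
    a <- m$atoms
    sel <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(d))) {
      sel <- sel | (a$chain == d$chain[i] & a$resno >= d$first[i] & a$resno <= d$last[i])
    }
    atoms[[length(atoms) + 1]] <- a[sel, ]
    domains[[length(domains) + 1]] <- d
    seen <- c(seen, d$label)
  }
  structure_model(dplyr::bind_rows(atoms), dplyr::bind_rows(domains))
}

# Orthonormal inertia frame of a point cloud: columns are the principal
# axes ordered long -> short (long axis = smallest-inertia eigenvector).
# Signs are fixed deterministically from the coordinates themselves so the
# frame is equivariant under rigid motions: the long axis points from the
# first to the last point, the mid axis towards the first point relative
# to the centroid, and the third completes a right-handed set.
inertia_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 points for an inertia frame")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  C <- crossprod(X) / n
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  if ((vals[1] - vals[2]) < 1e-8 * max(vals[1], 1e-12) ||
      (vals[2] - vals[3]) < 1e-8 * max(vals[1], 1e-12)) {
    stop("degenerate inertia tensor: point cloud has no unique principal axes")
  }
  long <- e$vectors[, 1]   # largest covariance eigenvalue = long axis
  if (sum(long * (xyz[n, ] - xyz[1, ])) < 0) long <- -long
  mid <- e$vectors[, 2]
  # equivariant sign rule: cubed projections (skewness), first point as tie-break
  s3 <- sum((X %*% mid)^3)
  if (abs(s3) > 1e-9) {
    if (s3 < 0) mid <- -mid
  } else if (sum(mid * (xyz[1, ] - ctr)) < 0) {
    mid <- -mid
  }
  third <- c(long[2] * mid[3] - long[3] * mid[2],
             long[3] * mid[1] - long[1] * mid[3],
             long[1] * mid[2] - long[2] * mid[1])
  cbind(long, mid, third)
}

# rotation matrix -> unit quaternion (w, x, y, z)
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

#' Tilt and twist between two domains
#'
#' Decomposes the rigid rotation carrying domain A's internal frame onto
#' domain B's into a tilt and a twist. Each domain's frame comes from the
#' C-alpha inertia tensor (long axis = principal axis of largest spatial
#' extent, sign fixed N to C). The package's fixed convention:
#' tilt = angle between the two long axes; twist = the swing-twist
#' component of the inter-domain rotation about domain A's long axis
#' (the rotation "about the filament axis" that survives after the tilt
#' swing is removed). A domain paired with itself gives tilt 0, twist 0;
#' a copy rotated about its own long axis by an angle gives exactly that
#' twist with zero tilt.
#'
#' @param model A [structure_model()].
#' @param domain_a,domain_b Domain labels (each needs >= 3 C-alpha
#'   atoms).
#' @return A one-row tibble: `domain_a`, `domain_b`, `tilt_deg` in
#'   `[0, 180]`, `twist_deg` in `(-180, 180]`, `centroid_distance`
#'   (Angstrom).
#' @export
tilt_twist <- function(model, domain_a, domain_b) {
  xa <- domain_atoms(model, domain_a)
  xb <- domain_atoms(model, domain_b)
  A <- inertia_frame(cbind(xa$x, xa$y, xa$z))
  B <- inertia_frame(cbind(xb$x, xb$y, xb$z))
  Q <- B %*% t(A)                     # carries A's frame onto B's
  long_a <- A[, 1]; long_b <- B[, 1]
  tilt <- acos(max(-1, min(1, sum(long_a * long_b)))) * 180 / pi
  q <- rot_to_quat(Q)
  proj <- sum(q[2:4] * long_a)        # swing-twist about A's long axis
  twist <- 2 * atan2(proj, q[1]) * 180 / pi
  if (twist <= -180) twist <- twist + 360
  if (twist > 180) twist <- twist - 360
  ca <- colMeans(cbind(xa$x, xa$y, xa$z))
  cb <- colMeans(cbind(xb$x, xb$y, xb$z))
  tibble::tibble(
    domain_a = domain_a, domain_b = domain_b,
    tilt_deg = tilt, twist_deg = twist,
    centroid_distance = sqrt(sum((ca - cb)^2))
  )
}

#' Tilt/twist table for consecutive domains
#'
#' @param model A [structure_model()] with ordered domains.
#' @return A tibble with one row per consecutive domain pair.
#' @export
consecutive_arrangements <- function(model) {
  labs <- unique(model$domains$label)
  if (length(labs) < 2) stop("need at least two domains")
  purrr::map_dfr(seq_len(length(labs) - 1), function(i) {
    tilt_twist(model, labs[i], labs[i + 1])
  })
}
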