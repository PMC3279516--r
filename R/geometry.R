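#' Labeled atomic/bead coordinate model with domain boundaries
#'
#' @param atoms Tibble with columns `chain`, `resno` (integer), `atom`
#'   (atom name, e.g. "CA"), `element`, `x`, `y`, `z` (Angstrom).
#' @param domains Tibble with columns `label`, `chain`, `first`, `last`
#'   (1-based author residue numbers, inclusive), ordered N to C along
#'   the filament.
#' @return A list of class `structure_model`.
#' @export
structure_model <- function(atoms, domains = NULL) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("chain", "resno", "atom", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("`atoms` missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("`atoms` is empty")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom positions must be finite")
  }
  if (is.null(domains)) {
    domains <- tibble::tibble(label = character(0), chain = character(0),
                              first = integer(0), last = integer(0))
  }
  domains <- tibble::as_tibble(domains)
  if (nrow(domains)) {
    reqd <- c("label", "chain", "first", "last")
    missd <- setdiff(reqd, names(domains))
    if (length(missd)) stop("`domains` missing column(s): ", paste(missd, collapse = ", "))
    for (i in seq_len(nrow(domains))) {
      sel <- atoms$chain == domains$chain[i] &
        atoms$resno >= domains$first[i] & atoms$resno <= domains$last[i]
      if (!any(sel)) {
        stop("domain '", domains$label[i], "' selects no atoms")
      }
    }
  }
  structure(list(atoms = atoms, domains = domains), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x$atoms), " atoms, ",
      nrow(x$domains), " domain(s)\n", sep = "")
  invisible(x)
}

# atoms of one labelled domain
domain_atoms <- function(model, label, calpha_only = TRUE) {
  d <- model$domains[model$domains$label == label, ]
  if (nrow(d) == 0) stop("no domain labelled '", label, "'")
  a <- model$atoms
  sel <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(d))) {
    sel <- sel | (a$chain == d$chain[i] & a$resno >= d$first[i] & a$resno <= d$last[i])
  }
  a <- a[sel, ]
  if (calpha_only) a <- a[a$atom == "CA", ]
  if (nrow(a) == 0) {
    stop("domain '", label, "' has no ", if (calpha_only) "C-alpha " else "", "atoms")
  }
  a
}

#' Read a PDB coordinate file
#'
#' Parses standard PDB via bio3d and enforces the package's coordinate
#' dialect: ATOM records of the first model only; alternate locations
#' other than blank or 'A' dropped; 1-based author residue numbering
#' preserved; insertion codes rejected; malformed coordinate fields
#' reported with the offending line number.
#'
#' @param path Path to a PDB file.
#' @param domains Optional domain boundary tibble (see
#'   [structure_model()]).
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, domains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- which(startsWith(lines, "ATOM ") | startsWith(lines, "ATOM\t") |
                        grepl("^ATOM  ", lines))
  # stop at the end of the first MODEL if the file has several
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) atom_lines <- atom_lines[atom_lines < endmdl[1]]
  if (!length(atom_lines)) stop("no ATOM records in ", path)
  for (ln in atom_lines) {
    coords <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      stop("malformed coordinate fields on line ", ln, " of ", path)
    }
    icode <- substring(lines[ln], 27, 27)
    if (icode != " ") {
      stop("insertion codes are not supported (line ", ln, " of ", path, ")")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  atoms <- tibble::tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    atom = as.character(at$elety),
    element = as.character(at$elesy),
    x = at$x, y = at$y, z = at$z
  )
  structure_model(atoms, domains)
}

#' Write a structure model as a minimal PDB file
#'
#' Fixture writer: emits standard fixed-column ATOM records (occupancy 1,
#' B-factor 0) terminated by END. Coordinates are written to 3 decimals,
#' the PDB precision.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom), a$atom)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, "ALA", substr(a$chain, 1, 1), a$resno,
    a$x, a$y, a$z, 1, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Domain centroids in filament order
#'
#' Centroid of the C-alpha positions of each labelled domain (the
#' reproducible proxy for a center of gravity), or the mass-weighted
#' all-atom centroid behind `weighting = "mass"`.
#'
#' @param model A [structure_model()] with non-empty domain boundaries.
#' @param weighting `"calpha"` (unweighted C-alpha mean, default) or
#'   `"mass"` (all atoms, element-mass weighted).
#' @param merge Optional character vector of two domain labels to merge
#'   into a single centroid (e.g. the two halves of a dimerisation
#'   module, so that the filament is seen as nine rigid bodies instead of
#'   ten domains).
#' @return A tibble `label`, `x`, `y`, `z` (Angstrom), in domain order.
#' @export
domain_centroids <- function(model, weighting = c("calpha", "mass"),
                             merge = NULL) {
  stopifnot(inherits(model, "structure_model"))
  weighting <- match.arg(weighting)
  if (nrow(model$domains) == 0) stop("model has no domain boundaries")
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  labels <- unique(model$domains$label)
  cent <- purrr::map_dfr(labels, function(lab) {
    a <- domain_atoms(model, lab, calpha_only = (weighting == "calpha"))
    w <- if (weighting == "mass") {
      m <- masses[a$element]
      m[is.na(m)] <- 12.011
      m
    } else {
      rep(1, nrow(a))
    }
    tibble::tibble(label = lab,
                   x = sum(w * a$x) / sum(w),
                   y = sum(w * a$y) / sum(w),
                   z = sum(w * a$z) / sum(w))
  })
  if (!is.null(merge)) {
    stopifnot(length(merge) == 2, all(merge %in% cent$label))
    i <- sort(match(merge, cent$label))
    merged <- tibble::tibble(label = paste(merge, collapse = "+"),
                             x = mean(cent$x[i]), y = mean(cent$y[i]),
                             z = mean(cent$z[i]))
    cent[i[1], ] <- merged
    cent <- cent[-i[2], ]
  }
  cent
}

#' Neighbor distance statistics of ordered centroids
#'
#' Mean, standard deviation and count of the distances between centroids
#' `k` apart in filament order (pooling intra- and inter-molecular pairs,
#' which the ordered list already interleaves).
#'
#' @param centroids A tibble with `x`, `y`, `z` in filament order (from
#'   [domain_centroids()]).
#' @param order Neighbor order `k >= 1` (vectorised).
#' @return A tibble `order`, `mean`, `sd`, `n_pairs` (Angstrom).
#' @export
neighbor_distance_stats <- function(centroids, order = 1) {
  xyz <- as.matrix(centroids[, c("x", "y", "z")])
  n <- nrow(xyz)
  purrr::map_dfr(order, function(k) {
    if (k < 1 || k != round(k)) stop("`order` must be a positive integer")
    if (k > n - 1) stop("order ", k, " needs at least ", k + 1, " centroids")
    i <- seq_len(n - k)
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[i + k, , drop = FALSE])^2))
    tibble::tibble(order = k, mean = mean(d),
                   sd = if (length(d) > 1) stats::sd(d) else 0,
                   n_pairs = length(d))
  })
}

#' Pair-distance distribution p(r) of a coordinate model
#'
#' Histogram of all unordered C-alpha pairwise distances, with the radius
#' of gyration (root mean square distance from the centroid) and the
#' maximum dimension Dmax. Counts are unnormalised.
#'
#' @param model A [structure_model()] (or a numeric matrix of points,
#'   n x 3).
#' @param bin_width Bin width, Angstrom.
#' @return A tibble of class `distance_distribution` with columns `r_lo`,
#'   `r_hi`, `count`, and attributes `rg` and `dmax` (Angstrom).
#' @export
pair_distance_distribution <- function(model, bin_width = 2) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  xyz <- model_points(model)
  if (nrow(xyz) < 2) stop("p(r) is undefined for fewer than 2 points")
  d <- as.numeric(stats::dist(xyz))
  dmax <- max(d)
  ctr <- colMeans(xyz)
  rg <- sqrt(mean(rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)))
  edges <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  # left-closed bins [lo, hi): a distance exactly on an edge counts upward
  counts <- graphics::hist(d, breaks = edges, plot = FALSE, right = FALSE)$counts
  out <- tibble::tibble(r_lo = utils::head(edges, -1),
                        r_hi = edges[-1],
                        count = counts)
  structure(out, class = c("distance_distribution", class(out)),
            rg = rg, dmax = dmax)
}

model_points <- function(model) {
  if (inherits(model, "structure_model")) {
    a <- model$atoms[model$atoms$atom == "CA", ]
    if (nrow(a) == 0) a <- model$atoms
    cbind(a$x, a$y, a$z)
  } else {
    m <- as.matrix(model)
    stopifnot(ncol(m) == 3)
    m
  }
}

#' Radius of gyration and maximum dimension of a distance distribution
#'
#' @param x A `distance_distribution`.
#' @param ... Unused.
#' @return A one-row tibble with `rg` and `dmax` in Angstrom.
#' @export
glance.distance_distribution <- function(x, ...) {
  tibble::tibble(rg = attr(x, "rg"), dmax = attr(x, "dmax"))
}

#' Local maxima of a pair-distance distribution
#'
#' Positions (bin midpoints) of local maxima of p(r) after light
#' smoothing, optionally restricted to distances beyond the main
#' intramodule peak. Used to read off the periodic maxima that repeating
#' domain spacings imprint on p(r).
#'
#' @param dd A `distance_distribution`.
#' @param from Ignore maxima below this distance, Angstrom.
#' @param smooth Half-width (bins) of the moving-average smoother.
#' @return Numeric vector of maxima positions, Angstrom.
#' @export
distribution_maxima <- function(dd, from = 0, smooth = 1) {
  mid <- (dd$r_lo + dd$r_hi) / 2
  y <- dd$count
  if (smooth > 0) {
    w <- 2 * smooth + 1
    y <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    y[is.na(y)] <- dd$count[is.na(y)]
  }
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1))
  mid[is_max & mid >= from & y > 0]
}
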