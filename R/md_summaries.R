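#' A single structure frame
#'
#' Coordinates are in nm; masses in amu default to 1 so that unweighted and
#' mass-weighted formulas coincide unless real masses are supplied.
#'
#' @param coordinates N x 3 numeric matrix (nm).
#' @param masses N positive masses (amu). Default 1 each.
#' @param atom_labels optional N character labels.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(coordinates, masses = rep(1, nrow(coordinates)),
                            atom_labels = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3 || nrow(coordinates) < 1) {
    stop("coordinates must be an N x 3 matrix with N >= 1", call. = FALSE)
  }
  if (any(!is.finite(coordinates))) stop("coordinates must be finite", call. = FALSE)
  if (length(masses) != nrow(coordinates) || any(masses <= 0)) {
    stop("masses must be positive, one per atom", call. = FALSE)
  }
  if (!is.null(atom_labels) && length(atom_labels) != nrow(coordinates)) {
    stop("atom_labels must have one entry per atom", call. = FALSE)
  }
  structure(list(coordinates = coordinates, masses = as.numeric(masses),
                 atom_labels = atom_labels),
            class = "structure_frame")
}

as_frame <- function(x) {
  if (inherits(x, "structure_frame")) x else structure_frame(as.matrix(x))
}

#' An ordered multi-frame trajectory
#'
#' @param frames list of [structure_frame()] objects with identical atom count.
#' @param times frame times in ps, strictly increasing; defaults to 0, 1, ...
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, times = seq_along(frames) - 1) {
  frames <- lapply(frames, as_frame)
  n_atoms <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(n_atoms)) != 1) {
    stop("all frames must have the same atom count", call. = FALSE)
  }
  if (length(times) != length(frames) || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame", call. = FALSE)
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' A per-frame scalar observable series
#'
#' @param times frame times in ps.
#' @param values per-frame values in the observable's units.
#' @param observable observable name, e.g. `"rmsd_nm"`, `"rg_nm"`,
#'   `"sasa_nm2"`, `"hbonds_protein_ligand"`.
#' @return tibble of class `frame_series` with columns `time`, `value`.
#' @export
frame_series <- function(times, values, observable = "other") {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(times), value = as.numeric(values))
  attr(out, "observable") <- observable
  class(out) <- c("frame_series", class(out))
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the mass-weighted
#' RMSD between a mobile and a reference frame, via SVD of the weighted
#' cross-covariance with reflection correction (the returned rotation always
#' has determinant +1). Degenerate geometries (all atoms collinear, where the
#' in-line rotation is not unique) fall back to a translation-only fit and
#' are flagged.
#'
#' @param mobile,reference [structure_frame()] objects (or N x 3 matrices)
#'   with equal atom counts; the reference frame's masses weight the fit.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3:
#'   aligned = mobile \%*\% rotation + translation), `rmsd` (nm) and
#'   `degenerate` flag.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mob <- as_frame(mobile)
  ref <- as_frame(reference)
  P <- mob$coordinates
  Q <- ref$coordinates
  if (nrow(P) != nrow(Q)) stop("atom counts differ", call. = FALSE)
  w <- ref$masses
  wsum <- sum(w)
  cp <- colSums(P * w) / wsum
  cq <- colSums(Q * w) / wsum
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  C <- t(Pc * w) %*% Qc
  sv <- svd(C)
  degenerate <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-10) < 2
  if (degenerate && sv$d[1] <= 1e-300) {
    # all atoms coincide with the centroid in one of the frames
    R <- diag(3)
  } else if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  aligned <- Pc %*% R
  rmsd <- sqrt(sum(w * rowSums((aligned - Qc)^2)) / wsum)
  translation <- as.numeric(cq - cp %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd,
       degenerate = degenerate)
}

select_atoms <- function(frame, selection) {
  if (is.null(selection)) return(frame)
  n <- nrow(frame$coordinates)
  if (any(selection < 1) || any(selection > n)) {
    stop("selection indices out of range", call. = FALSE)
  }
  structure_frame(frame$coordinates[selection, , drop = FALSE],
                  frame$masses[selection],
                  if (!is.null(frame$atom_labels)) frame$atom_labels[selection])
}

#' Per-frame RMSD series against a fixed reference
#'
#' Each frame is optimally superposed onto the reference with
#' [kabsch_superpose()] (so rigid-body motion contributes nothing) and the
#' minimised RMSD is recorded.
#'
#' @param traj a [trajectory()].
#' @param reference reference frame; defaults to the first frame.
#' @param selection optional atom index vector (e.g. backbone atoms).
#' @return a [frame_series()] with observable `"rmsd_nm"`.
#' @export
rmsd_series <- function(traj, reference = traj$frames[[1]], selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- select_atoms(as_frame(reference), selection)
  values <- vapply(traj$frames, function(f) {
    kabsch_superpose(select_atoms(f, selection), ref)$rmsd
  }, numeric(1))
  frame_series(traj$times, values, "rmsd_nm")
}

#' Per-atom root-mean-square fluctuation
#'
#' Removes global rigid motion by one round of superposition: frames are
#' first aligned to the initial frame, their unweighted mean structure is
#' taken, every original frame is re-aligned onto that mean, and the RMSF of
#' atom i is the root of the mean squared displacement from its mean aligned
#' position.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection optional atom index vector.
#' @return numeric vector of per-atom fluctuations (nm).
#' @export
rmsf_per_atom <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2) {
    stop("RMSF needs at least 2 frames", call. = FALSE)
  }
  frames <- lapply(traj$frames, select_atoms, selection = selection)
  ref0 <- frames[[1]]
  aligned_once <- lapply(frames, function(f) {
    fit <- kabsch_superpose(f, ref0)
    f$coordinates %*% fit$rotation + matrix(fit$translation, nrow(f$coordinates),
                                            3, byrow = TRUE)
  })
  mean_structure <- Reduce(`+`, aligned_once) / length(aligned_once)
  mean_frame <- structure_frame(mean_structure, frames[[1]]$masses)
  aligned <- lapply(frames, function(f) {
    fit <- kabsch_superpose(f, mean_frame)
    f$coordinates %*% fit$rotation + matrix(fit$translation, nrow(f$coordinates),
                                            3, byrow = TRUE)
  })
  mean_pos <- Reduce(`+`, aligned) / length(aligned)
  msd <- Reduce(`+`, lapply(aligned, function(x) rowSums((x - mean_pos)^2))) /
    length(aligned)
  sqrt(msd)
}

#' Radius of gyration
#'
#' Mass-weighted spread about the centre of mass:
#' Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i ).
#'
#' @param frame a [structure_frame()] or N x 3 matrix.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame) {
  f <- as_frame(frame)
  w <- f$masses
  com <- colSums(f$coordinates * w) / sum(w)
  centred <- sweep(f$coordinates, 2, com)
  sqrt(sum(w * rowSums(centred^2)) / sum(w))
}

#' Geometric hydrogen-bond criterion
#'
#' Defaults follow the common simulation-package convention:
#' donor-acceptor distance <= 0.35 nm and H-D-A angle <= 30 degrees.
#'
#' @param max_da_distance maximum donor-acceptor distance (nm).
#' @param max_angle maximum hydrogen-donor-acceptor angle (degrees).
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_angle = 30) {
  stopifnot(max_da_distance > 0, max_angle > 0)
  structure(list(max_da_distance = max_da_distance, max_angle = max_angle),
            class = "hbond_criterion")
}

#' Count geometric hydrogen bonds in a frame
#'
#' Counts donor-acceptor pairs for which some donor hydrogen satisfies the
#' distance and angle criterion; each donor-acceptor pair is counted at most
#' once regardless of how many hydrogens qualify.
#'
#' @param frame a [structure_frame()].
#' @param donors 2-column integer matrix of (donor, hydrogen) atom indices.
#' @param acceptors integer vector of acceptor atom indices.
#' @param criterion an [hbond_criterion()].
#' @return integer count.
#' @export
count_hbonds <- function(frame, donors, acceptors, criterion = hbond_criterion()) {
  f <- as_frame(frame)
  xyz <- f$coordinates
  n <- nrow(xyz)
  donors <- matrix(as.integer(donors), ncol = 2)
  acceptors <- as.integer(acceptors)
  idx <- c(donors, acceptors)
  if (any(idx < 1) || any(idx > n)) stop("atom indices out of range", call. = FALSE)
  if (any(donors[, 1] == donors[, 2])) {
    stop("donor and hydrogen must be distinct atoms", call. = FALSE)
  }
  counted <- character(0)
  for (i in seq_len(nrow(donors))) {
    d <- donors[i, 1]
    h <- donors[i, 2]
    for (a in acceptors) {
      if (a == d) next
      da <- xyz[a, ] - xyz[d, ]
      dist_da <- sqrt(sum(da^2))
      if (dist_da > criterion$max_da_distance) next
      dh <- xyz[h, ] - xyz[d, ]
      cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * dist_da)
      cosang <- min(1, max(-1, cosang))
      if (acos(cosang) * 180 / pi <= criterion$max_angle) {
        counted <- union(counted, paste(d, a))
      }
    }
  }
  length(counted)
}

#' Summary statistics of a scalar series after equilibration
#'
#' Mean, population standard deviation (the "mean +/- sd" convention of MD
#' summary tables), min, max and count over frames at or after the skip time.
#'
#' @param series a [frame_series()] or data frame with `time`, `value`.
#' @param equilibration_skip discard frames with time < this value (ps).
#' @return list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
series_summary <- function(series, equilibration_skip = 0) {
  keep <- series$time >= equilibration_skip
  x <- series$value[keep]
  if (length(x) == 0) {
    stop("no frames remain after the equilibration skip", call. = FALSE)
  }
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)), min = min(x), max = max(x),
       n = length(x))
}

#' Parse a GROMACS-style XVG scalar series
#'
#' Lines starting with `#` or `@` are metadata and are skipped; of the data
#' lines, the first column is time (ps) and the second the observable value.
#'
#' @param path path to the .xvg file.
#' @param observable observable name for the returned series.
#' @return a [frame_series()].
#' @export
parse_xvg <- function(path, observable = "other") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^[[:space:]]*[#@]", lines) &
                        nzchar(trimws(lines))]
  if (length(data_lines) == 0) {
    stop(sprintf("no data lines in %s", path), call. = FALSE)
  }
  fields <- strsplit(trimws(data_lines), "[[:space:]]+")
  times <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  values <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  if (any(is.na(times)) || any(is.na(values))) {
    stop(sprintf("unparseable data line in %s", path), call. = FALSE)
  }
  frame_series(times, values, observable)
}

#' Write a scalar series in XVG layout
#'
#' @param series a [frame_series()] or data frame with `time`, `value`.
#' @param path output path.
#' @param title optional title comment.
#' @return the path, invisibly.
#' @export
write_xvg <- function(series, path, title = NULL) {
  header <- c(if (!is.null(title)) paste("#", title),
              "@ xaxis label \"Time (ps)\"")
  body <- sprintf("%.10g %.10g", series$time, series$value)
  writeLines(c(header, body), path)
  invisible(path)
}
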