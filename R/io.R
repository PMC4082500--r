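# File formats: PQR atom records, OpenDX scalar grids ("regular positions,
# regular connections" dialect, z-fastest value order), and a plain-text
# trajectory container.

#' Read a PQR file
#'
#' Whitespace-separated ATOM/HETATM records; the final two numeric fields of
#' each record are the partial charge (e) and radius (A), preceded by x, y,
#' z (A).  TER/REMARK/other records are skipped.
#'
#' @param path file path.
#' @return an [atom_set()]; element/residue metadata are kept in `$meta`.
#' @export
read_pqr <- function(path) {
  lines <- readLines(path)
  keep <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  n <- length(lines)
  pos <- matrix(NA_real_, n, 3)
  q <- r <- numeric(n)
  meta <- data.frame(record = character(n), serial = integer(n),
                     name = character(n), resname = character(n),
                     resid = character(n))
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (length(tok) < 8 || anyNA(tail(num, 5)))
      stop(sprintf("malformed PQR record at line %d", lineno[i]))
    m <- length(tok)
    pos[i, ] <- num[(m - 4):(m - 2)]
    q[i] <- num[m - 1]
    r[i] <- num[m]
    meta$record[i] <- tok[1]
    meta$serial[i] <- suppressWarnings(as.integer(tok[2]))
    meta$name[i] <- tok[3]
    meta$resname[i] <- if (m >= 9) tok[4] else ""
    meta$resid[i] <- tok[m - 5]
  }
  atom_set(pos, charges = q, radii = r, meta = meta)
}

#' Write a PQR file
#'
#' @param atoms an [atom_set()].
#' @param path output path.
#' @param resname residue name used when the atom set has no metadata.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(atoms, path, resname = "SPH") {
  stopifnot(inherits(atoms, "atom_set"))
  n <- n_atoms(atoms)
  meta <- atoms$meta
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("ATOM  %5d %-4s %-4s %5d    %8.3f %8.3f %8.3f %8.4f %7.4f",
                       if (!is.null(meta)) meta$serial[i] else i,
                       if (!is.null(meta)) meta$name[i] else "C",
                       if (!is.null(meta)) meta$resname[i] else resname,
                       1L,
                       atoms$positions[i, 1], atoms$positions[i, 2],
                       atoms$positions[i, 3], atoms$charges[i],
                       atoms$radii[i]), con)
  }
  writeLines("TER", con)
  writeLines("END", con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Accepts the "regular positions, regular connections" scalar dialect
#' written by common Poisson-Boltzmann solvers: three equal diagonal deltas,
#' values in z-fastest order.  The grid kind is taken from a
#' `# kind: <kind>` comment when present, overridable by argument.
#'
#' @param path file path.
#' @param kind grid kind override (see [potential_grid()]).
#' @return a [potential_grid()].
#' @export
read_dx <- function(path, kind = NULL) {
  lines <- readLines(path)
  cm <- grep("^#\\s*kind:", lines, value = TRUE)
  if (is.null(kind))
    kind <- if (length(cm)) trimws(sub("^#\\s*kind:", "", cm[1])) else "electrostatic"
  body <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", body, value = TRUE)
  if (!length(gp)) stop("not an OpenDX gridpositions file: ", path)
  counts <- as.integer(tail(strsplit(trimws(gp[1]), "\\s+")[[1]], 3))
  og <- grep("^origin", body, value = TRUE)
  origin <- as.numeric(tail(strsplit(trimws(og[1]), "\\s+")[[1]], 3))
  dl <- grep("^delta", body, value = TRUE)
  if (length(dl) != 3) stop("expected 3 delta lines")
  deltas <- t(vapply(dl, function(s)
    as.numeric(tail(strsplit(trimws(s), "\\s+")[[1]], 3)), numeric(3)))
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12) ||
      abs(deltas[1, 1] - deltas[2, 2]) > 1e-9 ||
      abs(deltas[1, 1] - deltas[3, 3]) > 1e-9)
    stop("only uniform cubic grids (equal diagonal deltas) are supported")
  spacing <- unname(deltas[1, 1])
  dstart <- grep("data follows", body)
  if (!length(dstart)) stop("no 'data follows' marker")
  nv <- prod(counts)
  vals <- numeric(0)
  i <- dstart[1] + 1
  while (length(vals) < nv && i <= length(body)) {
    if (grepl("^(object|attribute|component|end)", body[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) < nv) stop("truncated DX data section")
  # file order: x slowest, z fastest -> R column-major [i, j, k]
  arr <- aperm(array(vals[seq_len(nv)], dim = rev(counts)), c(3, 2, 1))
  potential_grid(arr, origin, spacing, kind = kind)
}

#' Write an OpenDX scalar grid
#'
#' @param grid a [potential_grid()].
#' @param path output path.
#' @param digits significant digits for the values (default 8).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, digits = 8) {
  stopifnot(inherits(grid, "potential_grid"))
  n <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# OpenDX scalar field written by gridbd"),
               sprintf("# kind: %s", grid$kind),
               sprintf("object 1 class gridpositions counts %d %d %d",
                       n[1], n[2], n[3]),
               sprintf("origin %.8g %.8g %.8g", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("delta %.8g 0 0", grid$spacing),
               sprintf("delta 0 %.8g 0", grid$spacing),
               sprintf("delta 0 0 %.8g", grid$spacing),
               sprintf("object 2 class gridconnections counts %d %d %d",
                       n[1], n[2], n[3]),
               sprintf("object 3 class array type double rank 0 items %d data follows",
                       prod(n))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  fmt <- formatC(vals, digits = digits, format = "g")
  full <- length(fmt) %/% 3
  if (full > 0) {
    m <- matrix(fmt[seq_len(3 * full)], ncol = 3, byrow = TRUE)
    writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(fmt) > 3 * full)
    writeLines(paste(fmt[(3 * full + 1):length(fmt)], collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Write a trajectory to a plain-text container
#'
#' One header block (box, timestep, seed), one `E` line per frame with the
#' per-term energies, and one `F` line per solute per frame with position,
#' periodic image counts and orientation quaternion.  Numbers carry full
#' double precision.
#'
#' @param traj a `bd_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gridbd trajectory",
               sprintf("# box %.17g periodic %d", traj$box$side,
                       as.integer(traj$box$periodic)),
               sprintf("# dt %.17g record_stride %d", traj$params$dt,
                       traj$params$record_stride),
               sprintf("# seed %s", if (is.null(traj$params$seed)) "NA"
                       else format(traj$params$seed)),
               "# E time el_grid dh_tail edesolv npdesolv softcore total",
               "# F time id x y z ix iy iz qw qx qy qz"), con)
  N <- n_solutes(traj)
  for (f in seq_len(n_frames(traj))) {
    e <- traj$energies[f, ]
    writeLines(sprintf("E %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                       e$time, e$electrostatic_grid, e$dh_tail, e$edesolv,
                       e$npdesolv, e$softcore, e$total), con)
    writeLines(sprintf("F %.17g %d %.17g %.17g %.17g %d %d %d %.17g %.17g %.17g %.17g",
                       traj$times[f], seq_len(N),
                       traj$positions[, 1, f], traj$positions[, 2, f],
                       traj$positions[, 3, f],
                       traj$images[, 1, f], traj$images[, 2, f],
                       traj$images[, 3, f],
                       traj$quaternions[, 1, f], traj$quaternions[, 2, f],
                       traj$quaternions[, 3, f], traj$quaternions[, 4, f]), con)
  }
  invisible(path)
}

#' Read a trajectory container written by [write_trajectory()]
#'
#' @param path file path.
#' @return a `bd_trajectory` (analysis fields only: positions, images,
#'   quaternions, energies, box, timestep).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hd <- lines[grepl("^#", lines)]
  bx <- strsplit(trimws(sub("^# box", "", hd[grepl("^# box", hd)][1])), "\\s+")[[1]]
  box <- box_spec(as.numeric(bx[1]), periodic = bx[3] == "1")
  dtl <- strsplit(trimws(sub("^# dt", "", hd[grepl("^# dt", hd)][1])), "\\s+")[[1]]
  dt <- as.numeric(dtl[1]); stride <- as.integer(dtl[3])
  eL <- lines[grepl("^E ", lines)]
  fL <- lines[grepl("^F ", lines)]
  em <- do.call(rbind, lapply(strsplit(eL, "\\s+"), function(x) as.numeric(x[-1])))
  energies <- as.data.frame(em)
  names(energies) <- c("time", "electrostatic_grid", "dh_tail", "edesolv",
                       "npdesolv", "softcore", "total")
  fm <- do.call(rbind, lapply(strsplit(fL, "\\s+"), function(x) as.numeric(x[-1])))
  N <- max(fm[, 2])
  nf <- nrow(fm) / N
  ord <- order(rep(seq_len(nf), each = N), fm[, 2])
  fm <- fm[ord, , drop = FALSE]
  positions <- array(0, c(N, 3, nf)); images <- array(0L, c(N, 3, nf))
  quats <- array(0, c(N, 4, nf))
  for (f in seq_len(nf)) {
    blk <- fm[((f - 1) * N + 1):(f * N), , drop = FALSE]
    positions[, , f] <- blk[, 3:5]
    images[, , f] <- as.integer(blk[, 6:8])
    quats[, , f] <- blk[, 9:12]
  }
  times <- energies$time
  params <- bd_params(dt = dt, n_steps = as.integer(round(max(times) / dt)),
                      record_every = dt * stride)
  structure(list(times = times, positions = positions, images = images,
                 quaternions = quats, energies = energies, phi = NULL,
                 box = box, solvent = NULL, params = params,
                 species = rep(1L, N), solutes = NULL,
                 D0t = NA_real_, D0r = NA_real_,
                 dh_cutoff = NA_real_, R_cut = NA_real_),
            class = "bd_trajectory")
}
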