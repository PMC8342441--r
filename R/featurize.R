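#' Activation order parameters of a receptor structure
#'
#' Two collective variables summarizing class A GPCR activation:
#' the Calpha distance between positions 5.55 (TM5) and 7.46 (TM7), and the
#' Calpha angle with vertex at 6.47 (TM6 kink, next to the 6.48 toggle) and
#' arms to 6.34 (intracellular TM6) and 2.41 (TM2). The distance tracks the
#' TM5/TM7 approach, the angle the outward swing of TM6 that opens the
#' transducer cavity. The vertex sits at the middle-listed residue 6.47; with
#' that convention inactive structures fall near (21.3 Å, 37°) and fully
#' active ones near (17.4 Å, 69°).
#'
#' @param structure a `pdb_structure`.
#' @param bw a `bw_map` resolving positions 5.55, 7.46, 6.34, 6.47, 2.41.
#' @return named numeric vector `c(distance = Å, angle = degrees)`.
#' @export
order_params <- function(structure, bw) {
  p555 <- bw_ca(structure, bw, "5.55")
  p746 <- bw_ca(structure, bw, "7.46")
  p634 <- bw_ca(structure, bw, "6.34")
  p647 <- bw_ca(structure, bw, "6.47")
  p241 <- bw_ca(structure, bw, "2.41")
  c(distance = sqrt(sum((p555 - p746)^2)),
    angle = vec_angle(p634 - p647, p241 - p647))
}

# angle (degrees) between two vectors; clamped arccos for numerical safety
vec_angle <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop("zero-length arm vector")
  ct <- sum(u * v) / (cu * cv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Order parameters for a sequence of frames
#'
#' @param frames list of `pdb_structure` objects (e.g. from
#'   `read_pdb(..., model = "all")`) with consistent residue indexing.
#' @param bw a `bw_map`.
#' @param dt frame spacing.
#' @return a [feature_trajectory()] with columns `distance`, `angle`.
#' @export
order_params_series <- function(frames, bw, dt = 1) {
  rows <- lapply(seq_along(frames), function(i) {
    tryCatch(order_params(frames[[i]], bw),
             error = function(e)
               stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  })
  feature_trajectory(do.call(rbind, rows), labels = c("distance", "angle"),
                     dt = dt)
}

#' Backbone phi/psi dihedrals, sin/cos expanded
#'
#' Computes phi (C- N CA C) and psi (N CA C N+) for every residue where the
#' four atoms exist and the peptide bond is intact (C-N distance < 2.5 Å;
#' chain breaks drop the affected dihedral with a message). Each angle is
#' expanded to (sin, cos) columns so the features are continuous across the
#' +/-180 deg wrap, which tICA requires.
#'
#' @param frames list of `pdb_structure` objects.
#' @param chain restrict to one chain id (default: all protein chains).
#' @param dt frame spacing.
#' @return a [feature_trajectory()] with columns
#'   `sin_phi_<res>`, `cos_phi_<res>`, `sin_psi_<res>`, `cos_psi_<res>`.
#' @export
backbone_dihedrals <- function(frames, chain = NULL, dt = 1) {
  if (inherits(frames, "pdb_structure")) frames <- list(frames)
  rows <- lapply(frames, function(s) dihedral_row(s, chain))
  labs <- names(rows[[1L]])
  for (r in rows) if (!identical(names(r), labs))
    stop("inconsistent residue coverage across frames")
  feature_trajectory(do.call(rbind, rows), labels = labs, dt = dt)
}

dihedral_row <- function(structure, chain = NULL) {
  a <- structure$atoms
  a <- a[!a$het & a$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  key <- paste(a$chain, a$resseq, a$icode)
  res <- unique(key)
  get_atom <- function(k, nm) {
    i <- which(key == k & a$name == nm)
    if (length(i) == 0L) return(NULL)
    c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
  }
  out <- c(); nms <- c()
  for (r in seq_along(res)) {
    N <- get_atom(res[r], "N"); CA <- get_atom(res[r], "CA")
    C <- get_atom(res[r], "C")
    lab <- gsub(" ", "_", trimws(res[r]))
    if (r > 1L) {
      Cp <- get_atom(res[r - 1L], "C")
      if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C)) {
        if (sqrt(sum((N - Cp)^2)) < 2.5) {
          phi <- dihedral_angle(Cp, N, CA, C)
          out <- c(out, sin(phi), cos(phi))
          nms <- c(nms, paste0(c("sin_phi_", "cos_phi_"), lab))
        } else {
          message("chain break before residue ", lab, ": phi dropped")
        }
      }
    }
    if (r < length(res)) {
      Nn <- get_atom(res[r + 1L], "N")
      if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn)) {
        if (sqrt(sum((Nn - C)^2)) < 2.5) {
          psi <- dihedral_angle(N, CA, C, Nn)
          out <- c(out, sin(psi), cos(psi))
          nms <- c(nms, paste0(c("sin_psi_", "cos_psi_"), lab))
        } else {
          message("chain break after residue ", lab, ": psi dropped")
        }
      }
    }
  }
  stats::setNames(out, nms)
}

#' Dihedral angle of four points (radians, IUPAC sign convention)
#'
#' @param p1,p2,p3,p4 xyz coordinate vectors.
#' @return angle in radians in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross3(b1, v) * w), sum(v * w))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
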