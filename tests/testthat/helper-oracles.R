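# Independent oracles and fixture builders. Everything here is deliberately
# written by a different route than the package code it checks.

# ---- quaternion-based superposition (Horn 1987), SVD-free ------------------
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2L, colMeans(mobile))
  B <- sweep(reference, 2L, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(e2, 0))
}

# ---- rigid motions ---------------------------------------------------------
rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}

# ---- NeRF internal-coordinate peptide builder ------------------------------
# Places atom D given A-B-C, bond length |CD|, angle B-C-D, dihedral A-B-C-D.
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Backbone with prescribed phi/psi (omega = 180); returns a pdb_structure.
build_peptide <- function(phi, psi, n_res = length(phi)) {
  stopifnot(length(phi) == n_res, length(psi) == n_res)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  coords <- list()
  # seed residue
  N1 <- c(0, 0, 0); CA1 <- c(bNCA, 0, 0)
  C1 <- nerf_place(c(0, 1, 0), N1, CA1, bCAC, aNCAC, 0)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (r in 2:n_res) {
    prev <- coords[[r - 1]]
    N <- nerf_place(prev$N, prev$CA, prev$C, bCN, aCACN, psi[r - 1])
    CA <- nerf_place(prev$CA, prev$C, N, bNCA, aCNCA, 180)  # omega trans
    C <- nerf_place(prev$C, N, CA, bCAC, aNCAC, phi[r])
    coords[[r]] <- list(N = N, CA = CA, C = C)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    do.call(rbind, lapply(c("N", "CA", "C"), function(nm) {
      xyz <- coords[[r]][[nm]]
      data.frame(serial = 0L, name = nm, altloc = " ", resname = "ALA",
                 chain = "A", resseq = r, icode = " ",
                 x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
                 element = substr(nm, 1, 1), het = FALSE,
                 stringsAsFactors = FALSE)
    }))
  }))
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, model = 1L), class = "pdb_structure")
}

# Synthetic receptor-like structure: 5 Calpha atoms at chosen positions for
# the order-parameter BW positions, plus filler.
synthetic_bw_structure <- function(coords, chain = "A") {
  # coords: named list "5.55","7.46","6.34","6.47","2.41" -> xyz
  resmap <- c("2.41" = 65L, "5.55" = 212L, "6.34" = 239L, "6.47" = 252L,
              "7.46" = 295L)
  atoms <- do.call(rbind, lapply(names(coords), function(pos) {
    xyz <- coords[[pos]]
    data.frame(serial = 0L, name = "CA", altloc = " ", resname = "ALA",
               chain = chain, resseq = resmap[[pos]], icode = " ",
               x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
               element = "C", het = FALSE, stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model = 1L), class = "pdb_structure")
}

# ---- grid threshold-connectivity oracle for minimum-energy paths -----------
# Lowest energy level at which two points are connected through grid cells
# with V <= level (4-neighbour flood fill); also reports whether a third
# point lies in the connected component at that level.
grid_saddle_level <- function(surface, p_from, p_to, p_via = NULL,
                              resolution = 120L, iters = 40L) {
  nx <- ny <- resolution
  x <- seq(surface$lower[1], surface$upper[1], length.out = nx)
  y <- seq(surface$lower[2], surface$upper[2], length.out = ny)
  V <- outer(seq_len(nx), seq_len(ny),
             Vectorize(function(i, j) surface$energy(c(x[i], y[j]))))
  cell <- function(p) c(which.min(abs(x - p[1])), which.min(abs(y - p[2])))
  a <- cell(p_from); b <- cell(p_to)
  via <- if (!is.null(p_via)) cell(p_via)
  connected <- function(level) {
    ok <- V <= level
    if (!ok[a[1], a[2]] || !ok[b[1], b[2]]) return(list(conn = FALSE))
    seen <- matrix(FALSE, nx, ny)
    seen[a[1], a[2]] <- TRUE
    frontier <- (a[2] - 1L) * nx + a[1]
    repeat {
      i <- (frontier - 1L) %% nx + 1L
      j <- (frontier - 1L) %/% nx + 1L
      nbr <- c((j - 1L) * nx + pmin(i + 1L, nx), (j - 1L) * nx + pmax(i - 1L, 1L),
               pmin(j, ny - 1L) * nx + i, pmax(j - 2L, 0L) * nx + i)
      nbr <- unique(nbr[ok[nbr] & !seen[nbr]])
      if (length(nbr) == 0L) break
      seen[nbr] <- TRUE
      frontier <- nbr
    }
    list(conn = seen[b[1], b[2]],
         via = if (!is.null(via)) seen[via[1], via[2]] else NA,
         seen = seen)
  }
  lo <- max(V[a[1], a[2]], V[b[1], b[2]]); hi <- max(V)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (connected(mid)$conn) hi <- mid else lo <- mid
  }
  res <- connected(hi)
  list(level = hi, via_connected = res$via,
       grid_dx = diff(x[1:2]), grid_dy = diff(y[1:2]))
}

# ---- Markov chain simulation oracles ---------------------------------------
simulate_chain <- function(TT, n_steps, start = 1L) {
  n <- nrow(TT)
  out <- integer(n_steps + 1L)
  out[1L] <- start
  cum <- t(apply(TT, 1L, cumsum))
  u <- runif(n_steps)
  for (t in seq_len(n_steps)) {
    out[t + 1L] <- findInterval(u[t], cum[out[t], ]) + 1L
  }
  out
}

mc_first_passage <- function(TT, from, to, n_chains = 1e4, max_steps = 1e4) {
  n <- nrow(TT)
  cum <- t(apply(TT, 1L, cumsum))
  times <- numeric(n_chains)
  for (c in seq_len(n_chains)) {
    s <- from
    t <- 0L
    while (!(s %in% to) && t < max_steps) {
      s <- findInterval(runif(1), cum[s, ]) + 1L
      t <- t + 1L
    }
    times[c] <- t
  }
  times
}

mc_committor <- function(TT, state, A, B, n_chains = 1e4, max_steps = 1e5) {
  cum <- t(apply(TT, 1L, cumsum))
  hitB <- logical(n_chains)
  for (c in seq_len(n_chains)) {
    s <- state
    for (t in seq_len(max_steps)) {
      s <- findInterval(runif(1), cum[s, ]) + 1L
      if (s %in% A) { hitB[c] <- FALSE; break }
      if (s %in% B) { hitB[c] <- TRUE; break }
    }
  }
  mean(hitB)
}

# ---- independent operational-model implementation --------------------------
# Literal transcription of the printed explicit equation, no shared code.
operational_reference_impl <- function(basal, Emax, n, LogKA, LogR, X,
                                       branch = c("Y2", "Y1")) {
  branch <- match.arg(branch)
  A <- 10^X
  if (branch == "Y1") {
    operate <- ((1 + A) / ((10^LogR) * A))^n
  } else {
    operate <- ((1 + A / (10^LogKA)) / ((10^LogR) * A))^n
  }
  basal + (Emax - basal) / (1 + operate)
}

# ---- misc ------------------------------------------------------------------
expect_equal_tol <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %.3g < %.3g",
                              max(abs(object - expected)), tol))
}
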