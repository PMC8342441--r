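#' Read a PDB file
#'
#' Fixed-width parser for ATOM/HETATM/MODEL/ENDMDL/TER records (PDB v3.3
#' columns). HETATM records (fusion proteins, ligands, waters) are retained
#' but flagged `het = TRUE` so they can be excluded from featurization, as is
#' done when stripping antagonists and crystallization chaperones from
#' receptor structures. No renumbering: residue numbers and insertion codes
#' are kept verbatim.
#'
#' @param path PDB file.
#' @param model model number to keep for multi-model files; `NULL` (default)
#'   keeps the first model; `"all"` returns a list of structures, one per
#'   model.
#' @return a `structure` object: list with `atoms` data.frame (serial, name,
#'   altloc, resname, chain, resseq, icode, x, y, z, occupancy, element, het)
#'   and `model` id. With `model = "all"`, a list of such objects.
#' @export
read_pdb <- function(path, model = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_id <- integer(length(lines))
  cur <- 1L
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (any(is_model)) {
    cur <- 0L
    for (i in seq_along(lines)) {
      if (is_model[i]) cur <- suppressWarnings(
        as.integer(trimws(substr(lines[i], 7L, 14L))))
      model_id[i] <- if (is.na(cur)) 0L else cur
      if (is_end[i]) cur <- 0L
    }
  } else model_id[] <- 1L
  al <- lines[is_atom]
  if (length(al) == 0L) stop("no ATOM/HETATM records in ", path)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(!is.finite(v))
    if (what %in% c("x", "y", "z") && length(bad))
      stop(sprintf("malformed ATOM record (bad %s) at line %d", what,
                   which(is_atom)[bad[1L]]))
    v
  }
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(al, 7L, 11L))),
    name = trimws(substr(al, 13L, 16L)),
    altloc = substr(al, 17L, 17L),
    resname = trimws(substr(al, 18L, 20L)),
    chain = substr(al, 22L, 22L),
    resseq = suppressWarnings(as.integer(substr(al, 23L, 26L))),
    icode = substr(al, 27L, 27L),
    x = num(31L, 38L, "x"), y = num(39L, 46L, "y"), z = num(47L, 54L, "z"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(al, 55L, 60L)))
      ifelse(is.finite(o), o, 1)
    },
    element = trimws(substr(al, 77L, 78L)),
    het = substr(al, 1L, 6L) == "HETATM",
    model = model_id[is_atom],
    stringsAsFactors = FALSE)
  if (anyNA(atoms$resseq))
    stop("malformed ATOM record (bad residue number) at line ",
         which(is_atom)[which(is.na(atoms$resseq))[1L]])
  models <- unique(atoms$model)
  mk <- function(m) {
    a <- atoms[atoms$model == m, , drop = FALSE]
    a$model <- NULL
    rownames(a) <- NULL
    structure(list(atoms = a, model = m), class = "pdb_structure")
  }
  if (identical(model, "all")) return(lapply(models, mk))
  mk(if (is.null(model)) models[1L] else model)
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pdb_structure> model %s: %d atoms (%d HETATM), chains: %s\n",
              x$model, nrow(a), sum(a$het),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

#' Write a structure back to PDB
#'
#' Emits ATOM/HETATM records for the fields the parser reads, so
#' read -> write -> read is a fixpoint on those fields.
#'
#' @param structure a `pdb_structure`.
#' @param path output file.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  name4 <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
                  sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), a$serial, name4, a$altloc, a$resname,
    a$chain, a$resseq, a$icode, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Look up one Calpha coordinate
#'
#' Resolves altloc duplicates by highest occupancy (ties broken by altloc
#' letter order). HETATM records are excluded.
#'
#' @param structure a `pdb_structure`.
#' @param chain chain id.
#' @param resseq residue sequence number.
#' @param icode insertion code (default blank).
#' @return length-3 xyz vector (Å).
#' @export
get_ca <- function(structure, chain, resseq, icode = " ") {
  a <- structure$atoms
  sel <- !a$het & a$name == "CA" & a$chain == chain & a$resseq == resseq &
    a$icode == icode
  hit <- a[sel, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop(sprintf("no Calpha for chain %s residue %d%s", chain, resseq,
                 trimws(icode)))
  if (nrow(hit) > 1L) {
    hit <- hit[order(-hit$occupancy, hit$altloc), , drop = FALSE][1L, ]
  }
  c(hit$x, hit$y, hit$z)
}

#' Ballesteros-Weinstein position table
#'
#' Reads a two-column delimited table mapping generic GPCR positions
#' ("helix.position", e.g. "3.50") to "chain:resnum" in a specific structure.
#' The packaged default (`bw_table_at1r()`) covers the human angiotensin II
#' type 1 receptor positions used by the activation order parameters.
#'
#' @param path tab- or whitespace-delimited file with columns
#'   `position`, `residue` (`chain:resnum`); `#` comments allowed.
#' @return a `bw_map`: data.frame with columns `position`, `chain`, `resseq`.
#' @export
read_bw_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("position", "residue") %in% names(df)))
    stop("BW table needs columns `position` and `residue`")
  parts <- strsplit(as.character(df$residue), ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("bad residue spec: ", df$residue[bad][1L])
  out <- data.frame(position = as.character(df$position),
                    chain = vapply(parts, `[`, "", 1L),
                    resseq = as.integer(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$position)) stop("duplicate BW positions in table")
  class(out) <- c("bw_map", class(out))
  out
}

#' @rdname read_bw_table
#' @export
bw_table_at1r <- function() {
  read_bw_table(system.file("extdata", "at1r_bw_map.tsv",
                            package = "conformpath", mustWork = TRUE))
}

#' Validate a BW map against a structure
#'
#' Verifies that every mapped position has a Calpha atom in the structure.
#'
#' @param structure a `pdb_structure`.
#' @param bw_table a `bw_map` from [read_bw_table()].
#' @return the validated `bw_map` (invisibly identical content).
#' @export
resolve_bw <- function(structure, bw_table) {
  for (i in seq_len(nrow(bw_table))) {
    tryCatch(get_ca(structure, bw_table$chain[i], bw_table$resseq[i]),
             error = function(e)
               stop(sprintf("BW position %s does not resolve: %s",
                            bw_table$position[i], conditionMessage(e)),
                    call. = FALSE))
  }
  bw_table
}

bw_ca <- function(structure, bw_table, position) {
  i <- match(position, bw_table$position)
  if (is.na(i)) stop("BW position not in table: ", position)
  get_ca(structure, bw_table$chain[i], bw_table$resseq[i])
}

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` (SVD-based, determinant-corrected to exclude
#' reflections).
#'
#' @param mobile,reference n x 3 (or n x d) coordinate matrices, n >= 3.
#' @return list with `rotation` (d x d, det +1), `translation` (applied as
#'   `mobile %*% rotation + translation`), `rmsd`, and `transformed`
#'   coordinates.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("point sets must have equal dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (max(sv$d) <= 0 ||
      sum(sv$d > 1e-10 * max(sv$d)) < ncol(mobile) - 1L)
    stop("degenerate (rank-deficient) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(rep(1, ncol(mobile) - 1L), d))
  R <- sv$u %*% D %*% t(sv$v)
  transformed <- sweep(A %*% R, 2L, cr, FUN = "+")
  rmsd <- sqrt(mean(rowSums((transformed - reference)^2)))
  list(rotation = R, translation = cr - as.numeric(cm %*% R),
       rmsd = rmsd, transformed = transformed)
}

#' Pairwise RMSD after optimal superposition
#'
#' @param frames list of n x 3 coordinate matrices with consistent atom order.
#' @param superpose superpose each pair before the RMSD (default TRUE);
#'   FALSE computes plain coordinate RMSD (use for feature-space frames).
#' @return symmetric distance matrix.
#' @export
pairwise_rmsd <- function(frames, superpose = TRUE) {
  n <- length(frames)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- if (superpose)
      kabsch_superpose(frames[[i]], frames[[j]])$rmsd
    else sqrt(mean(rowSums((as.matrix(frames[[i]]) -
                            as.matrix(frames[[j]]))^2)))
  }
  d
}
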