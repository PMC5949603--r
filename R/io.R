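# PDB input/output (via bio3d) and a small pipeline driver.

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA123 <- stats::setNames(names(AA321), AA321)

#' Read a backbone structure from a PDB file
#'
#' First model of multi-model files, first chain by default, altloc "A" (or
#' blank) preferred. Extracts N, CA, C, O and CB atoms; residues missing
#' backbone atoms are reported in an attribute rather than failing.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default first chain present.
#' @return A \code{bbp_structure}; residue positions renumbered 1..n in
#'   file order, original numbering kept in \code{residues$resno}.
#' @export
read_backbone_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (is.null(chain)) chain <- a$chain[1]
  keep <- (is.na(a$chain) | a$chain == chain) &
    a$elety %in% c("N", "CA", "C", "O", "CB") &
    (is.na(a$alt) | a$alt %in% c("", "A"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no backbone atoms found in ", path)
  resno <- unique(a$resno)
  idx <- match(a$resno, resno)
  code <- vapply(resno, function(r) {
    nm <- a$resid[a$resno == r][1]
    v <- AA321[nm]
    if (is.na(v)) "X" else unname(v)
  }, "")
  residues <- data.frame(position = seq_along(resno), resno = resno,
                         code = code, chirality = "L",
                         stringsAsFactors = FALSE)
  atoms <- data.frame(residue = idx, atom = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  s <- backbone_structure(residues, atoms)
  have <- table(factor(atoms$atom[atoms$atom %in% c("N", "CA", "C", "O")],
                       levels = c("N", "CA", "C", "O")), atoms$residue[
                         atoms$atom %in% c("N", "CA", "C", "O")])
  missing <- residues$position[colSums(have > 0) < 4]
  attr(s, "missing_backbone") <- missing
  s
}

#' Write a backbone structure to a PDB file
#'
#' @param s A \code{bbp_structure}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_backbone_pdb <- function(s, path) {
  at <- s$atoms
  code <- toupper(s$residues$code[at$residue])
  resid <- ifelse(code %in% names(AA123), AA123[code], "UNK")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue, resid = resid, elety = at$atom,
                   chain = "A")
  invisible(path)
}

#' Run the analysis pipeline over the packaged fixtures
#'
#' Executes the requested stages and writes one CSV per stage plus a JSON
#' summary (when jsonlite is available) under \code{out_dir}. Stage
#' failures are isolated and collected rather than aborting the run.
#'
#' @param stages Subset of \code{c("mass", "enumerate", "tempcoeff")}.
#' @param out_dir Output directory (created if needed); NULL for no files.
#' @param seed Seed recorded in the summary (the fixture stages are
#'   deterministic).
#' @return List with per-stage results, \code{failures}, and \code{seed}.
#' @export
run_pipeline <- function(stages = c("mass", "enumerate", "tempcoeff"),
                         out_dir = NULL, seed = 1L) {
  results <- list(seed = seed, failures = character(0))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    df
  }
  for (st in stages) {
    res <- tryCatch(switch(st,
      mass = emit("mass", fixture_mass_table()),
      enumerate = {
        topo <- enumerate_topologies(enum_config())
        topo$total_raw <- format(count_sequences(topo, enum_config()))
        emit("enumerate", topo)
      },
      tempcoeff = {
        tc <- load_fixtures("temp_coeffs")
        tc$class <- classify_temp_coeff(tc$coeff)
        emit("tempcoeff", tc)
      },
      stop("unknown stage: ", st)),
      error = function(e) {
        results$failures <<- c(results$failures,
                               paste0(st, ": ", conditionMessage(e)))
        NULL
      })
    results[[st]] <- res
  }
  if (!is.null(out_dir) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(seed = seed, stages = stages,
                              failures = results$failures),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
  }
  results
}

# Mass report over every fixture sequence: formula, neutral mass, m/z for
# the printed adduct, at 2 and 4 decimals.
fixture_mass_table <- function() {
  sq <- load_fixtures("sequences")
  rows <- lapply(seq_len(nrow(sq)), function(i) {
    g <- parse_bbp(sq$notation[i],
                   c_term = if (sq$c_term[i] == "amide") "amide" else "acid",
                   thioether = isTRUE(sq$thioether[i]))
    f <- formula_of(g)
    M <- monoisotopic_mass(f)
    mz <- adduct_mz(M, sq$printed_adduct[i])
    data.frame(id = sq$id[i], formula = ef_string(f), neutral_mass = M,
               adduct = sq$printed_adduct[i],
               mz_2dp = mz$mz2, mz_4dp = round_half_up(mz$mz, 4),
               printed_mz = sq$printed_mz[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
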