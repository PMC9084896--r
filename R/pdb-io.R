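# PDB-format input/output for multiconformer models.
#
# Reading goes through bio3d::read.pdb for the atom records; the CRYST1 and
# REMARK 2 header fields, which bio3d does not expose, are scanned from the
# raw lines. Writing emits fixed-column PDB text directly so that the
# conformer-grouped model (blank shared atoms followed by labelled altloc
# blocks) round-trips exactly.

#' Read a multiconformer PDB file
#'
#' Parses ATOM/HETATM records and assembles alternate-location groups into
#' conformers. Atoms with a blank altloc are replicated logically into every
#' conformer of their residue (they are shared); the conformer occupancy is
#' taken from its labelled atoms and is authoritative. CRYST1 is parsed into
#' the space group and unit cell; resolution is read from REMARK 2 when
#' present, otherwise the `resolution` argument is used.
#'
#' Only MODEL 1 of a multi-model (NMR-style) file is read, with a warning.
#'
#' @param path Path to a PDB-format file.
#' @param resolution Resolution in Angstrom, used when the file has no
#'   REMARK 2 record.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, resolution = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # malformed-record pre-scan: coordinate records must carry parseable fields
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stop(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
  }

  space_group <- NA_character_
  cell <- NULL
  cry <- lines[startsWith(lines, "CRYST1")]
  if (length(cry)) {
    cry <- cry[1]
    cell <- as.numeric(c(substr(cry, 7, 15), substr(cry, 16, 24),
                         substr(cry, 25, 33), substr(cry, 34, 40),
                         substr(cry, 41, 47), substr(cry, 48, 54)))
    space_group <- trimws(substr(cry, 56, 66))
  }
  res_ang <- if (is.null(resolution)) NA_real_ else as.numeric(resolution)
  rem2 <- lines[startsWith(lines, "REMARK   2 RESOLUTION")]
  if (length(rem2)) {
    tail_txt <- substr(rem2[1], 23, 80)
    v <- suppressWarnings(as.numeric(regmatches(
      tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))))
    if (length(v) && !is.na(v)) res_ang <- v
  }

  nmodel <- sum(startsWith(lines, "MODEL "))
  if (nmodel > 1) warning("multi-model file: only MODEL 1 read")

  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                         multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$elesy[is.na(at$elesy)] <- ""
  # fall back to the first character of the atom name when the element
  # column is empty (common in minimal synthetic files)
  miss <- !nzchar(at$elesy)
  at$elesy[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)

  key <- paste(at$chain, at$resno, at$insert, at$resid, at$type, sep = "\r")
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))

  residues <- list()
  ligands <- list()
  for (idx in groups) {
    g <- at[idx, , drop = FALSE]
    hetero <- g$type[1] == "HETATM"
    mk_atoms <- function(rows) {
      atom_table(name = rows$elety, element = rows$elesy, x = rows$x,
                 y = rows$y, z = rows$z, occupancy = rows$o, b = rows$b,
                 altloc = rows$alt, is_hetero = hetero)
    }
    labels <- sort(unique(g$alt[g$alt != ""]))
    blank <- g[g$alt == "", , drop = FALSE]
    if (!length(labels)) {
      cfs <- list(conformer("", blank$o[1], mk_atoms(blank)))
    } else {
      cfs <- lapply(labels, function(L) {
        lab <- g[g$alt == L, , drop = FALSE]
        conformer(L, lab$o[1], rbind(mk_atoms(blank), mk_atoms(lab)))
      })
    }
    res <- multiconf_residue(chain = g$chain[1], seqnum = g$resno[1],
                             aa = g$resid[1], conformers = cfs,
                             icode = g$insert[1], hetero = hetero)
    if (hetero) ligands[[length(ligands) + 1L]] <- res
    else residues[[length(residues) + 1L]] <- res
  }

  structure_model(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
                  residues = residues, ligands = ligands,
                  space_group = space_group, cell = cell,
                  resolution = res_ang)
}

format_atom_name <- function(name, element) {
  if (nchar(name) > 4) stop("atom name longer than 4 characters: ", name)
  # standard alignment: element symbol in columns 13-14
  if (nchar(name) < 4 && nchar(element) == 1) sprintf(" %-3s", name)
  else sprintf("%-4s", name)
}

#' Write a multiconformer model as PDB
#'
#' Emits fixed-column PDB text: CRYST1, REMARK 2 resolution when known, then
#' ATOM/HETATM records. For each residue, shared (blank-altloc) atoms are
#' written once, followed by one block per conformer with the altloc column
#' populated; occupancies and B-factors are written at standard precision
#' (\%6.2f).
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  out <- character(0)
  if (!is.na(model$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                          model$resolution))
  if (!is.null(model$cell))
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          model$cell[1], model$cell[2], model$cell[3],
                          model$cell[4], model$cell[5], model$cell[6],
                          ifelse(is.na(model$space_group), "P 1",
                                 model$space_group)))
  serial <- 0L
  emit <- function(res) {
    rectype <- if (res$hetero) "HETATM" else "ATOM  "
    at <- residue_atoms_unique(res)
    lines <- character(nrow(at))
    for (i in seq_len(nrow(at))) {
      serial <<- serial + 1L
      lines[i] <- sprintf(
        "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rectype, serial, format_atom_name(at$name[i], at$element[i]),
        at$altloc[i], res$aa, res$chain, res$seqnum, res$icode,
        at$x[i], at$y[i], at$z[i], at$occupancy[i], at$b[i],
        sprintf("%2s", at$element[i]))
    }
    lines
  }
  for (res in model$residues) out <- c(out, emit(res))
  if (length(model$residues)) out <- c(out, "TER")
  for (res in model$ligands) out <- c(out, emit(res))
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Split a multiconformer model by alternate conformation
#'
#' For every distinct altloc label in the model, builds a single-conformer
#' model containing, for each residue, the conformer with that label together
#' with all atoms that have no alternative conformation. A residue lacking
#' the label contributes its highest-occupancy conformer (ties broken by the
#' lexicographically smallest altloc). A model with no altlocs yields exactly
#' one copy.
#'
#' @param model A [structure_model()].
#' @return Named list of single-conformer [structure_model()]s, one per
#'   altloc label.
#' @export
split_by_altloc <- function(model) {
  grp <- c(model$residues, model$ligands)
  labels <- sort(unique(unlist(lapply(grp, function(res)
    setdiff(vapply(res$conformers, `[[`, "", "altloc"), "")))))
  if (!length(labels)) return(stats::setNames(list(model), ""))

  pick <- function(res, L) {
    alts <- vapply(res$conformers, `[[`, "", "altloc")
    i <- which(alts == L)
    if (!length(i)) {
      occ <- vapply(res$conformers, `[[`, 0, "occupancy")
      i <- which(occ == max(occ))
      i <- i[order(alts[i])][1]  # tie -> smallest altloc
    }
    res$conformers <- res$conformers[i[1]]
    res
  }
  out <- lapply(labels, function(L) {
    m <- model
    m$id <- paste0(model$id, "_alt", L)
    m$residues <- lapply(model$residues, pick, L = L)
    m$ligands <- lapply(model$ligands, pick, L = L)
    m
  })
  stats::setNames(out, labels)
}
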