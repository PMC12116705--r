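# File formats: peak-list TSV (plus a Sparky-like dialect), prediction and
# PRE observation TSVs, and an NMR-STAR 3.1 chemical-shift loop subset for
# BMRB-style deposition and retrieval.

#' Read a 2D methyl peak list
#'
#' Dialects: \code{"tsv"} — tab-separated with header columns \code{id},
#' \code{dH}, \code{dC} and optional \code{intensity}, \code{form};
#' \code{"sparky"} — whitespace-separated \code{Assignment w1 w2 Height}
#' columns with w1 = 13C ppm and w2 = 1H ppm. Lines starting with '#' carry
#' metadata (\code{# spectrum=...}, \code{# scheme=...}) and are honoured on
#' read. Malformed rows are reported with their line numbers.
#'
#' @param path input file.
#' @param dialect "tsv" (default) or "sparky".
#' @return a \code{\link{peaklist}}.
#' @export
read_peaklist <- function(path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(m) == 0) default else sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  spectrum <- get_meta("spectrum", "unknown")
  scheme <- get_meta("scheme", NA_character_)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0) stop("no header line in ", path)
  header_line <- body_idx[1]
  body <- lines[body_idx[-1]]
  body_lines <- body_idx[-1]
  if (dialect == "tsv") {
    cols <- strsplit(lines[header_line], "\t")[[1]]
    rows <- strsplit(body, "\t")
  } else {
    cols <- strsplit(trimws(lines[header_line]), "\\s+")[[1]]
    rows <- strsplit(trimws(body), "\\s+")
  }
  if (dialect == "sparky") {
    want <- c("Assignment", "w1", "w2", "Height")
    if (!all(tolower(want[1:3]) %in% tolower(cols)))
      stop("sparky dialect needs columns Assignment, w1, w2")
  } else if (!all(c("id", "dH", "dC") %in% cols)) {
    stop("tsv dialect needs columns id, dH, dC")
  }
  parse_num <- function(x, what, lineno) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is.na(x) & nzchar(x)
    if (any(bad))
      stop("non-numeric ", what, " at line(s) ",
           paste(lineno[bad], collapse = ", "), " of ", path)
    v
  }
  if (length(body) == 0) {
    df <- data.frame(id = character(), dH = numeric(), dC = numeric(),
                     intensity = numeric(), form = character(),
                     stringsAsFactors = FALSE)
    return(peaklist(df, spectrum = spectrum, scheme = scheme))
  }
  nbad <- which(lengths(rows) < length(cols))
  if (length(nbad) > 0)
    stop("malformed row(s) at line(s) ",
         paste(body_lines[nbad], collapse = ", "), " of ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- cols[seq_len(ncol(m))]
  if (dialect == "sparky") {
    lc <- tolower(colnames(m))
    df <- data.frame(
      id = m[, which(lc == "assignment")],
      dC = parse_num(m[, which(lc == "w1")], "w1 shift", body_lines),
      dH = parse_num(m[, which(lc == "w2")], "w2 shift", body_lines),
      intensity = if ("height" %in% lc)
        abs(parse_num(m[, which(lc == "height")], "height", body_lines))
        else 1,
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      id = m[, "id"],
      dH = parse_num(m[, "dH"], "dH shift", body_lines),
      dC = parse_num(m[, "dC"], "dC shift", body_lines),
      intensity = if ("intensity" %in% cols)
        parse_num(m[, "intensity"], "intensity", body_lines) else 1,
      form = if ("form" %in% cols) m[, "form"] else "unknown",
      stringsAsFactors = FALSE)
  }
  peaklist(df, spectrum = spectrum, scheme = scheme)
}

#' Write a peak list as TSV
#'
#' @param peaks a \code{\link{peaklist}}.
#' @param path output file.
#' @export
write_peaklist <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# spectrum=", attr(peaks, "spectrum")), con)
  if (!is.na(attr(peaks, "scheme")))
    writeLines(paste0("# scheme=", attr(peaks, "scheme")), con)
  utils::write.table(as.data.frame(peaks), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write chemical-shift prediction tables
#'
#' TSV with columns \code{methyl_id}, \code{nucleus}, \code{value_ppm},
#' \code{uncertainty_ppm} (blank allowed) and \code{source}.
#'
#' @param path file path.
#' @return data.frame with columns \code{methyl_id}, \code{nucleus},
#'   \code{value}, \code{uncertainty}, \code{source}.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  data.frame(methyl_id = df$methyl_id, nucleus = df$nucleus,
             value = df$value_ppm, uncertainty = df$uncertainty_ppm,
             source = df$source, stringsAsFactors = FALSE)
}

#' @rdname read_predictions
#' @param predictions data.frame as returned by \code{read_predictions} (an
#'   \code{uncertainty} column may be absent or NA).
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(methyl_id = predictions$methyl_id,
                    nucleus = predictions$nucleus,
                    value_ppm = predictions$value,
                    uncertainty_ppm = if (is.null(predictions$uncertainty))
                      NA_real_ else predictions$uncertainty,
                    source = if (is.null(predictions$source)) NA_character_
                             else predictions$source,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write PRE observation tables
#'
#' TSV with columns \code{methyl_id}, \code{I_para}, \code{I_dia},
#' \code{quantifiable}. The intensity ratio is computed on read and defined
#' only for quantifiable rows with positive diamagnetic intensity.
#'
#' @param path file path.
#' @return data.frame: \code{methyl_id}, \code{I_para}, \code{I_dia},
#'   \code{quantifiable}, \code{ratio}.
#' @export
read_pre_observations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  q <- as.logical(df$quantifiable) & is.finite(df$I_dia) & df$I_dia > 0
  df$quantifiable <- q
  df$ratio <- ifelse(q, df$I_para / df$I_dia, NA_real_)
  df
}

#' @rdname read_pre_observations
#' @param obs data.frame with \code{methyl_id}, \code{I_para}, \code{I_dia},
#'   \code{quantifiable}.
#' @export
write_pre_observations <- function(obs, path) {
  utils::write.table(
    obs[, c("methyl_id", "I_para", "I_dia", "quantifiable")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# methyl pseudo name -> (carbon, proton) NMR-STAR atom ids
.star_atoms <- function(pseudo) {
  stem <- substring(pseudo, 2)  # QD1 -> D1, QE -> E
  list(C = paste0("C", stem), H = paste0("H", stem))
}

#' Export an assignment as an NMR-STAR 3.1 chemical-shift loop
#'
#' Writes one \code{Atom_chem_shift} row per assigned nucleus (two per
#' methyl: the methyl carbon, e.g. CD1, and its proton, e.g. HD1), with the
#' shifts taken from the assigned peak positions. Stereo-unresolved geminal
#' methyls receive ambiguity code 2, all others code 1.
#'
#' @param state an \code{assignment_state}.
#' @param methyls the methyl table behind the state.
#' @param path output file.
#' @param entry_id data-block name.
#' @param ambiguous methyl ids whose stereo assignment is unresolved.
#' @return \code{path}, invisibly.
#' @export
write_nmrstar <- function(state, methyls, path, entry_id = "assignments",
                          ambiguous = character()) {
  map <- state$map
  rows <- character(0)
  k <- 0L
  if (nrow(map) > 0) {
    i <- match(map$peak_id, state$peaks$id)
    j <- match(map$methyl_id, methyls$methyl_id)
    ord <- order(methyls$resno[j], methyls$label[j])
    for (r in ord) {
      m <- methyls[j[r], ]
      pseudo <- sub("^.*-", "", map$methyl_id[r])
      at <- .star_atoms(pseudo)
      amb <- if (map$methyl_id[r] %in% ambiguous) 2L else 1L
      for (nuc in c("C", "H")) {
        k <- k + 1L
        val <- if (nuc == "C") state$peaks$dC[i[r]] else state$peaks$dH[i[r]]
        rows <- c(rows, sprintf("      %d %d %s %s %s %.3f . %d",
                                k, m$resno, m$restype, at[[nuc]], nuc, val,
                                amb))
      }
    }
  }
  doc <- c(
    paste0("data_", entry_id),
    "",
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_framecode  assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.ID            1",
    "",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Atom_type",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Val_err",
    "      _Atom_chem_shift.Ambiguity_code",
    rows,
    "   stop_",
    "save_")
  writeLines(doc, path)
  invisible(path)
}

#' Read an NMR-STAR chemical-shift loop
#'
#' Parses the \code{Atom_chem_shift} loop of an NMR-STAR 3.1 document and
#' returns the methyl-relevant rows. Both proton naming conventions (HD1
#' and QD1/MD1) are accepted; atoms that do not correspond to an ILVM methyl
#' nucleus are skipped with a warning summary.
#'
#' @param path NMR-STAR file.
#' @return data.frame: \code{methyl_id}, \code{resno}, \code{restype},
#'   \code{atom}, \code{nucleus}, \code{shift}, \code{ambiguity}.
#' @export
read_nmrstar <- function(path) {
  lines <- readLines(path)
  loop_start <- grep("^\\s*loop_\\s*$", lines)
  if (length(loop_start) == 0) stop("no loop_ found in ", path)
  out <- NULL
  for (ls in loop_start) {
    tags <- character(0)
    i <- ls + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    tagname <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines) && !grepl("^\\s*stop_", lines[i])) {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !grepl("^#", ln))
        rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
      i <- i + 1
    }
    if (length(rows) == 0) {
      out <- data.frame(methyl_id = character(), resno = integer(),
                        restype = character(), atom = character(),
                        nucleus = character(), shift = numeric(),
                        ambiguity = integer(), stringsAsFactors = FALSE)
      next
    }
    m <- do.call(rbind, rows)
    colnames(m) <- tagname[seq_len(ncol(m))]
    need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
    if (!all(need %in% colnames(m)))
      stop("chemical-shift loop lacks required tags in ", path)
    atom_raw <- m[, "Atom_ID"]
    # normalize proton pseudo conventions: QD1/MD1 -> HD1 etc.
    atom <- sub("^[QM]", "H", atom_raw)
    restype <- m[, "Comp_ID"]
    resno <- as.integer(m[, "Comp_index_ID"])
    # which (restype, atom) are ILVM methyl nuclei?
    def <- .methyl_def
    keyC <- paste(def$restype, def$carbon)
    keyH <- paste(def$restype, paste0("H", substring(def$carbon, 2)))
    key <- paste(restype, atom)
    isC <- key %in% keyC
    isH <- key %in% keyH
    keep <- isC | isH
    if (any(!keep))
      warning(sum(!keep), " non-methyl rows skipped", call. = FALSE)
    if (!any(keep)) next
    def_idx <- ifelse(isC[keep], match(key[keep], keyC),
                      match(key[keep], keyH))
    amb <- if ("Ambiguity_code" %in% colnames(m))
      suppressWarnings(as.integer(m[keep, "Ambiguity_code"])) else
      NA_integer_
    part <- data.frame(
      methyl_id = .methyl_id(restype[keep], resno[keep],
                             def$pseudo[def_idx]),
      resno = resno[keep], restype = restype[keep], atom = atom[keep],
      nucleus = ifelse(isC[keep], "C", "H"),
      shift = as.numeric(m[keep, "Val"]), ambiguity = amb,
      stringsAsFactors = FALSE)
    out <- if (is.null(out)) part else rbind(out, part)
  }
  if (is.null(out)) stop("no Atom_chem_shift loop found in ", path)
  rownames(out) <- NULL
  out
}
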