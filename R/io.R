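# PDB / mmCIF input and PDB output -----------------------------------------

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a structure from a PDB or mmCIF file
#'
#' Reads all ATOM/HETATM records of the first model. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first in file),
#' waters are dropped, and hetero ligands are retained but flagged as
#' non-polymer (`het`). Author chain/residue numbering is kept as-is.
#'
#' @param path file path.
#' @param format `"auto"` (by extension and content), `"PDB"` or `"mmCIF"`.
#' @param id optional structure id; defaults to the file base name.
#' @return an [rna_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmCIF"
              else if (ext %in% c("pdb", "ent")) "PDB"
              else if (any(grepl("^_atom_site\\.", lines))) "mmCIF"
              else "PDB"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  at <- if (format == "PDB") parse_pdb_lines(lines, path) else parse_cif_lines(lines, path)
  at <- at[!(toupper(at$resname) %in% WATER_NAMES), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure (no non-water atoms): ", path)
  at <- resolve_altloc(at)
  at$altloc <- NULL
  rna_structure(at, id = id, source_format = format)
}

parse_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    warning("multiple MODEL blocks in ", path, "; keeping MODEL 1 only")
  }
  if (length(model_starts) >= 1) {
    ends <- which(trimws(rec) == "ENDMDL")
    last <- if (length(ends) >= 1) ends[1] else length(lines)
    keepers <- seq(model_starts[1], last)
    lines <- lines[keepers]
    rec <- rec[keepers]
  }
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0) stop("no ATOM/HETATM records in ", path)
  ln <- lines[sel]
  num <- function(s, line_ids) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & trimws(s) != "")
    if (length(bad) > 0) {
      stop("unparseable numeric field in ", path, " at line ", line_ids[bad[1]],
           ": '", lines[line_ids[bad[1]]], "'")
    }
    v
  }
  resno <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  if (anyNA(resno)) {
    bad <- sel[which(is.na(resno))[1]]
    stop("unparseable residue number in ", path, " at line ", bad)
  }
  data.frame(
    chain = substr(ln, 22, 22),
    resno = resno,
    icode = trimws(substr(ln, 27, 27)),
    resname = trimws(substr(ln, 18, 20)),
    name = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    element = trimws(substr(ln, 77, 78)),
    x = num(substr(ln, 31, 38), sel),
    y = num(substr(ln, 39, 46), sel),
    z = num(substr(ln, 47, 54), sel),
    occ = ifelse(is.na(num(substr(ln, 55, 60), sel)), 1,
                 num(substr(ln, 55, 60), sel)),
    b = ifelse(is.na(num(substr(ln, 61, 66), sel)), 0,
               num(substr(ln, 61, 66), sel)),
    het = substr(ln, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF atom_site reader. Handles the loop_ layout with quoted
# tokens; that covers wwPDB-distributed coordinate files.
parse_cif_lines <- function(lines, path) {
  loop_rows <- which(trimws(lines) == "loop_")
  for (lr in loop_rows) {
    i <- lr + 1
    fields <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1
    }
    if (any(grepl("^_atom_site\\.", fields))) {
      data_lines <- character()
      while (i <= length(lines)) {
        l <- trimws(lines[i])
        if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
        data_lines <- c(data_lines, lines[i])
        i <- i + 1
      }
      return(cif_atom_table(fields, data_lines, path))
    }
  }
  stop("no _atom_site loop found in ", path)
}

cif_tokens <- function(line) {
  # whitespace-separated, honoring single/double quotes
  out <- character()
  s <- line
  pat <- "^\\s*(?:'([^']*)'|\"([^\"]*)\"|(\\S+))"
  repeat {
    m <- regexec(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) break
    parts <- regmatches(s, regexec(pat, s, perl = TRUE))[[1]]
    tok <- parts[parts != ""][-1][1]
    if (is.na(tok)) tok <- ""
    out <- c(out, tok)
    s <- substr(s, m[1] + attr(m, "match.length")[1], nchar(s))
    if (trimws(s) == "") break
  }
  out
}

cif_atom_table <- function(fields, data_lines, path) {
  fnames <- sub("^_atom_site\\.", "", fields)
  toks <- lapply(data_lines, cif_tokens)
  nf <- length(fields)
  ok <- vapply(toks, length, 1L) == nf
  if (!all(ok)) {
    stop("malformed _atom_site row in ", path, " (token count mismatch, row ",
         which(!ok)[1], ")")
  }
  m <- do.call(rbind, toks)
  colnames(m) <- fnames
  get <- function(primary, fallback = NULL, default = NA) {
    if (primary %in% fnames) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fnames) return(m[, fallback])
    rep(default, nrow(m))
  }
  undot <- function(v, default = "") ifelse(v %in% c(".", "?") | is.na(v), default, v)
  if ("pdbx_PDB_model_num" %in% fnames) {
    mods <- m[, "pdbx_PDB_model_num"]
    first <- mods[1]
    if (any(mods != first)) {
      warning("multiple models in ", path, "; keeping model ", first, " only")
      keep <- mods == first
      m <- m[keep, , drop = FALSE]
    }
  }
  get2 <- function(primary, fallback = NULL, default = NA) {
    if (primary %in% fnames) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fnames) return(m[, fallback])
    rep(default, nrow(m))
  }
  xyz <- function(fld) {
    v <- suppressWarnings(as.numeric(m[, fld]))
    if (anyNA(v)) stop("unparseable coordinate in ", path, " (_atom_site.", fld, ")")
    v
  }
  data.frame(
    chain = undot(get2("auth_asym_id", "label_asym_id"), "A"),
    resno = as.integer(undot(get2("auth_seq_id", "label_seq_id"), "0")),
    icode = undot(get2("pdbx_PDB_ins_code"), ""),
    resname = undot(get2("auth_comp_id", "label_comp_id"), "UNK"),
    name = undot(get2("auth_atom_id", "label_atom_id"), ""),
    altloc = undot(get2("label_alt_id"), ""),
    element = undot(get2("type_symbol"), ""),
    x = xyz("Cartn_x"), y = xyz("Cartn_y"), z = xyz("Cartn_z"),
    occ = suppressWarnings(as.numeric(undot(get2("occupancy"), "1"))),
    b = suppressWarnings(as.numeric(undot(get2("B_iso_or_equiv"), "0"))),
    het = get2("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
}

resolve_altloc <- function(at) {
  if (!"altloc" %in% names(at) || all(at$altloc == "")) return(at)
  key <- paste(at$chain, at$resno, at$icode, at$name, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    best <- idx[which.max(at$occ[idx])]  # ties: first in file
    keep[setdiff(idx, best)] <- FALSE
  }
  # single-conformer altloc labels are harmless; just drop the flag
  at[keep, , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' Fixed-format PDB v3.3 ATOM/HETATM records; coordinates at 1e-3 A
#' precision (the format's own limit).
#'
#' @param structure an `rna_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  fmt_name <- function(nm, el) {
    # element-aligned atom names: 1-char elements indent one space
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           ifelse(nchar(el) >= 2, sprintf("%-4s", nm), sprintf(" %-3s", nm)))
  }
  el <- ifelse(at$element == "" | is.na(at$element),
               toupper(substr(sub("^[0-9]+", "", at$name), 1, 1)), at$element)
  lines <- sprintf("%-6s%5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(at$het, "HETATM", "ATOM"),
                   (seq_len(nrow(at)) - 1L) %% 99999L + 1L,
                   fmt_name(at$name, el), " ",
                   at$resname, at$chain, at$resno,
                   ifelse(at$icode == "", " ", at$icode),
                   at$x, at$y, at$z, at$occ, at$b, toupper(el))
  # TER between chains, END at the end
  chains <- at$chain
  out <- character(0)
  for (ch in unique(chains)) {
    out <- c(out, lines[chains == ch], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
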