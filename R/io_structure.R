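#' Read a macromolecular model from PDB or mmCIF
#'
#' The PDB reader parses CRYST1 plus ATOM/HETATM fixed-column records;
#' the mmCIF reader parses the `_cell`, `_symmetry` and `_atom_site`
#' categories. Unknown records/categories are ignored. Both dialects
#' require a unit cell and space group.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default: by file
#'   extension, `.cif`/`.mmcif` read as mmCIF).
#' @return An [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
}

#' Write a macromolecular model to PDB or mmCIF
#'
#' mmCIF is the canonical format and round-trips all in-scope fields;
#' PDB writing is best-effort (single-character chain ids required).
#'
#' @param model An [structure_model()].
#' @param path Output path.
#' @param format As in [read_structure()].
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "pdb") write_structure_pdb(model, path) else write_structure_mmcif(model, path)
  invisible(path)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (!length(cr))
    stop("missing CRYST1 record (unit cell and space group) in ", path)
  cr <- cr[1]
  cell <- unit_cell(as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
                    as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
                    as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54)))
  sg <- trimws(substr(cr, 56, 66))
  if (!nzchar(sg)) stop("missing space group symbol in CRYST1 record of ", path)
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(at)) {
    num <- function(from, to) {
      v <- suppressWarnings(as.numeric(trimws(substr(at, from, to))))
      v
    }
    atoms <- data.frame(
      chain = trimws(substr(at, 22, 22)),
      seqnum = suppressWarnings(as.integer(trimws(substr(at, 23, 26)))),
      icode = trimws(substr(at, 27, 27)),
      resname = trimws(substr(at, 18, 20)),
      atom = trimws(substr(at, 13, 16)),
      element = trimws(substr(at, 77, 78)),
      x = num(31, 38), y = num(39, 46), z = num(47, 54),
      occ = num(55, 60), b = num(61, 66),
      stringsAsFactors = FALSE)
    bad <- which(is.na(atoms$seqnum) | is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))
    if (length(bad))
      stop("malformed atom record at line: ", at[bad[1]])
    atoms$element[!nzchar(atoms$element)] <- guess_element(atoms$atom[!nzchar(atoms$element)])
    atoms$occ[is.na(atoms$occ)] <- 1
    atoms$b[is.na(atoms$b)] <- 20
  } else atoms <- empty_atom_table()
  structure_model(cell, space_group(sg), atoms)
}

write_structure_pdb <- function(model, path) {
  if (any(nchar(model$atoms$chain) > 1))
    stop("PDB writing requires single-character chain ids; use mmCIF")
  c_ <- model$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   c_$a, c_$b, c_$c, c_$alpha, c_$beta, c_$gamma,
                   model$spacegroup$symbol, 1)
  a <- model$atoms
  if (nrow(a)) {
    rec <- ifelse(a$category %in% c("water", "dummy", "other"), "HETATM", "ATOM  ")
    name4 <- ifelse(nchar(a$atom) < 4 & nchar(a$element) == 1,
                    sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
    lines <- c(lines, sprintf(
      "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(a)) %% 100000, name4, a$resname, a$chain,
      a$seqnum, ifelse(nzchar(a$icode), a$icode, " "),
      a$x, a$y, a$z, a$occ, a$b, toupper(a$element)))
  }
  writeLines(c(lines, "END"), path)
}

# --- minimal mmCIF tokenizer -------------------------------------------------

cif_tokenize <- function(line) {
  out <- character(0)
  i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      out <- c(out, substr(line, i, j - 1))
      i <- j
    }
  }
  out
}

# Parse an mmCIF file into (items, loops): items is a named character
# vector of non-loop tags; loops is a list of data frames keyed by
# category name.
cif_parse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  items <- character(0)
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "data_")) { i <- i + 1; next }
    if (line == "loop_") {
      tags <- character(0)
      i <- i + 1
      while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i]))
        i <- i + 1
      }
      vals <- character(0)
      while (i <= length(lines)) {
        l <- trimws(lines[i])
        if (!nzchar(l) || startsWith(l, "_") || l == "loop_" ||
            startsWith(l, "data_")) break
        vals <- c(vals, cif_tokenize(lines[i]))
        i <- i + 1
      }
      if (length(vals) %% length(tags) != 0)
        stop("malformed mmCIF loop (", length(vals), " values for ",
             length(tags), " tags) near row: ", vals[1])
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags
      cat_name <- sub("\\..*$", "", tags[1])
      loops[[cat_name]] <- df
    } else if (startsWith(line, "_")) {
      toks <- cif_tokenize(line)
      if (length(toks) >= 2) {
        items[toks[1]] <- paste(toks[-1], collapse = " ")
      } else if (i + 1 <= length(lines)) {
        items[toks[1]] <- trimws(lines[i + 1])
        i <- i + 1
      }
      i <- i + 1
      next
    } else i <- i + 1
  }
  list(items = items, loops = loops)
}

cif_item <- function(parsed, tag) {
  v <- parsed$items[tag]
  if (is.na(v)) NA_character_ else unname(v)
}

read_structure_mmcif <- function(path) {
  p <- cif_parse(path)
  need <- c("_cell.length_a", "_cell.length_b", "_cell.length_c",
            "_cell.angle_alpha", "_cell.angle_beta", "_cell.angle_gamma")
  vals <- suppressWarnings(as.numeric(vapply(need, function(t) cif_item(p, t), "")))
  if (any(is.na(vals)))
    stop("missing unit cell (_cell.*) in ", path)
  sg <- cif_item(p, "_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- cif_item(p, "_space_group.name_H-M_alt")
  if (is.na(sg)) stop("missing space group (_symmetry.space_group_name_H-M) in ", path)
  cell <- unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
  as_ <- p$loops[["_atom_site"]]
  if (is.null(as_)) {
    atoms <- empty_atom_table()
  } else {
    col <- function(tag, default = NULL) {
      full <- paste0("_atom_site.", tag)
      if (full %in% names(as_)) as_[[full]] else default
    }
    nr <- nrow(as_)
    atoms <- data.frame(
      chain = col("auth_asym_id", col("label_asym_id", rep("A", nr))),
      seqnum = suppressWarnings(as.integer(col("auth_seq_id", col("label_seq_id")))),
      icode = { ic <- col("pdbx_PDB_ins_code", rep("", nr)); ifelse(ic %in% c("?", "."), "", ic) },
      resname = col("label_comp_id"),
      atom = col("label_atom_id"),
      element = col("type_symbol", rep("", nr)),
      x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
      z = as.numeric(col("Cartn_z")),
      occ = as.numeric(col("occupancy", rep("1", nr))),
      b = as.numeric(col("B_iso_or_equiv", rep("20", nr))),
      stringsAsFactors = FALSE)
    if (any(is.na(atoms$seqnum)) || any(is.na(atoms$x)))
      stop("malformed _atom_site row in ", path)
  }
  structure_model(cell, space_group(sg), atoms)
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- "."
  needs <- grepl("[ '\"]", x)
  x[needs] <- paste0("\"", x[needs], "\"")
  x
}

write_structure_mmcif <- function(model, path) {
  c_ <- model$cell
  hdr <- c(
    "data_model",
    sprintf("_cell.length_a    %.6f", c_$a),
    sprintf("_cell.length_b    %.6f", c_$b),
    sprintf("_cell.length_c    %.6f", c_$c),
    sprintf("_cell.angle_alpha %.6f", c_$alpha),
    sprintf("_cell.angle_beta  %.6f", c_$beta),
    sprintf("_cell.angle_gamma %.6f", c_$gamma),
    sprintf("_symmetry.space_group_name_H-M '%s'", model$spacegroup$symbol))
  a <- model$atoms
  body <- character(0)
  if (nrow(a)) {
    body <- c(
      "loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_comp_id",
      "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
      "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
      "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      sprintf("%s %d %s %s %s %s %d %s %.6f %.6f %.6f %.6f %.6f",
              ifelse(a$category %in% c("water", "dummy", "other"), "HETATM", "ATOM"),
              seq_len(nrow(a)), cif_quote(toupper(a$element)), cif_quote(a$atom),
              cif_quote(a$resname), cif_quote(a$chain), a$seqnum,
              ifelse(nzchar(a$icode), a$icode, "?"),
              a$x, a$y, a$z, a$occ, a$b))
  }
  writeLines(c(hdr, body), path)
}
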