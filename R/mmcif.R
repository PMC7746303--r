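# Minimal mmCIF reader/writer.
#
# The reader extracts whole categories (notably atom_site and the assembly
# categories pdbx_struct_assembly_gen / pdbx_struct_oper_list) from a CIF
# block, tolerating quoted values, multi-line semicolon text fields and
# loop rows wrapped over several lines. It deliberately does not attempt
# dictionary validation. The writer emits atom_site records sufficient to
# round-trip the polymer model, plus optional assembly categories, so that
# synthetic fixtures are genuine mmCIF exercised through the same parser
# as real entries.

#' @keywords internal
.cifTokenizeLine <- function(line) {
  m <- gregexpr("\"[^\"]*\"|'[^']*'|\\S+", line)[[1L]]
  if (m[1L] == -1L) return(character(0))
  tok <- regmatches(line, list(m))[[1L]]
  # strip surrounding quotes
  q <- grepl("^(\"|').*\\1$", tok)
  tok[q] <- substr(tok[q], 2L, nchar(tok[q]) - 1L)
  # drop trailing comment tokens (a bare # starts a comment)
  cm <- which(tok == "#")
  if (length(cm)) tok <- tok[seq_len(cm[1L] - 1L)]
  tok
}

#' Read the categories of an mmCIF file
#'
#' Parses the first data block of an mmCIF file (optionally gzipped) into a
#' list of categories; each category is a character data.frame with one
#' column per item keyword. Both looped and key-value categories are
#' returned in the same shape (key-value categories have a single row).
#'
#' @param path File path (".gz" handled transparently).
#' @return Named list of data.frames keyed by category name (e.g.
#'   "atom_site"), plus attribute "block" with the data block name.
#' @export
readMmcif <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("parse error: empty CIF file: ", path)

  cats <- list()
  block <- NULL
  i <- 1L
  n <- length(lines)

  nextToken <- function() NULL  # placeholder for clarity

  readSemicolonBlock <- function() {
    # assumes lines[i] starts with ";"; returns the joined text value
    first <- sub("^;", "", lines[i])
    i <<- i + 1L
    buf <- first
    while (i <= n && !startsWith(lines[i], ";")) {
      buf <- c(buf, lines[i])
      i <<- i + 1L
    }
    if (i > n) stop("parse error: unterminated semicolon text block")
    i <<- i + 1L
    paste(buf, collapse = "\n")
  }

  storeItem <- function(cat, item, value) {
    df <- cats[[cat]]
    if (is.null(df)) df <- data.frame(row.names = 1L)
    df[[item]] <- value
    cats[[cat]] <<- df
  }

  while (i <= n) {
    line <- lines[i]
    trimmed <- trimws(line)
    if (trimmed == "" || startsWith(trimmed, "#")) { i <- i + 1L; next }
    if (startsWith(trimmed, "data_")) {
      if (!is.null(block)) break  # only the first block
      block <- sub("^data_", "", trimmed)
      i <- i + 1L
      next
    }
    if (trimmed == "loop_") {
      i <- i + 1L
      fields <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        fields <- c(fields, trimws(strsplit(trimws(lines[i]), "\\s+")[[1L]][1L]))
        i <- i + 1L
      }
      if (!length(fields)) stop("parse error: loop_ without item keywords near line ", i)
      values <- character(0)
      while (i <= n) {
        t2 <- trimws(lines[i])
        if (t2 == "" ) { i <- i + 1L; next }
        if (startsWith(lines[i], ";")) { values <- c(values, readSemicolonBlock()); next }
        if (startsWith(t2, "_") || t2 == "loop_" || startsWith(t2, "data_") ||
            startsWith(t2, "#")) {
          if (startsWith(t2, "#")) { i <- i + 1L; next }
          break
        }
        values <- c(values, .cifTokenizeLine(lines[i]))
        i <- i + 1L
      }
      if (length(values) %% length(fields) != 0L)
        stop("parse error: ragged loop for category ",
             sub("\\..*$", "", fields[1L]), " (", length(values),
             " values for ", length(fields), " items)")
      mat <- matrix(values, ncol = length(fields), byrow = TRUE)
      cat <- sub("^_", "", sub("\\..*$", "", fields[1L]))
      items <- sub("^[^.]*\\.", "", fields)
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- items
      cats[[cat]] <- df
      next
    }
    if (startsWith(trimmed, "_")) {
      tok <- .cifTokenizeLine(line)
      key <- tok[1L]
      if (length(tok) >= 2L) {
        value <- paste(tok[-1L], collapse = " ")
        i <- i + 1L
      } else {
        i <- i + 1L
        while (i <= n && trimws(lines[i]) == "") i <- i + 1L
        if (i <= n && startsWith(lines[i], ";")) {
          value <- readSemicolonBlock()
        } else if (i <= n) {
          value <- .cifTokenizeLine(lines[i])[1L]
          i <- i + 1L
        } else stop("parse error: dangling item ", key)
      }
      cat <- sub("^_", "", sub("\\..*$", "", key))
      item <- sub("^[^.]*\\.", "", key)
      storeItem(cat, item, value)
      next
    }
    stop("parse error: unexpected record near line ", i, ": ",
         substr(trimmed, 1L, 40L))
  }
  if (is.null(block)) stop("parse error: no data_ block in ", path)
  attr(cats, "block") <- block
  cats
}

#' Write a PolymerStructure as minimal mmCIF
#'
#' Emits atom_site records (label and auth numbering, full precision
#' coordinates) sufficient to round-trip the model through
#' \code{\link{loadStructure}}. Chain copies produced by assembly expansion
#' are not written; the asymmetric-unit content (operator "1") is emitted,
#' optionally together with assembly categories so that expansion can be
#' re-applied on load.
#'
#' @param structure A \linkS4class{PolymerStructure}.
#' @param path Output file path.
#' @param assemblies Optional list describing assemblies to declare:
#'   each element \code{list(id=, operators=list(id= list(rotation= 3x3,
#'   translation= length-3)), chains= character())}.
#' @param digits Coordinate decimals (default 3).
#' @return \code{path}, invisibly.
#' @export
writeMmcif <- function(structure, path, assemblies = NULL, digits = 3L) {
  res <- structure@residues
  atm <- structure@atoms
  keep <- res$operator[atm$res] == "1"
  atm <- atm[keep, , drop = FALSE]
  out <- c(sprintf("data_%s", structure@structureId), "#")

  if (!is.null(assemblies)) {
    out <- c(out,
      "loop_",
      "_pdbx_struct_assembly_gen.assembly_id",
      "_pdbx_struct_assembly_gen.oper_expression",
      "_pdbx_struct_assembly_gen.asym_id_list")
    for (a in assemblies) {
      out <- c(out, sprintf("%s %s %s", a$id,
                            paste(names(a$operators), collapse = ","),
                            paste(a$chains, collapse = ",")))
    }
    out <- c(out, "#",
      "loop_",
      "_pdbx_struct_oper_list.id",
      paste0("_pdbx_struct_oper_list.matrix[", rep(1:3, each = 3L), "][",
             rep(1:3, 3L), "]"),
      paste0("_pdbx_struct_oper_list.vector[", 1:3, "]"))
    seen <- character(0)
    for (a in assemblies) for (oid in names(a$operators)) {
      if (oid %in% seen) next
      seen <- c(seen, oid)
      op <- a$operators[[oid]]
      out <- c(out, paste(oid,
        paste(sprintf("%.6f", t(op$rotation)), collapse = " "),
        paste(sprintf("%.6f", op$translation), collapse = " ")))
    }
    out <- c(out, "#")
  }

  out <- c(out,
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_comp_id", "_atom_site.pdbx_PDB_model_num")

  if (nrow(atm)) {
    r <- res[atm$res, ]
    comp <- .token1to3(r$code)
    name <- atm$name
    qname <- ifelse(grepl("'", name), sprintf('"%s"', name), name)
    authChain <- if ("authChain" %in% names(r)) r$authChain else r$chain
    authSeq <- if ("authSeq" %in% names(r)) r$authSeq else r$seq
    fmt <- paste0("%.", digits, "f")
    out <- c(out, sprintf(
      "ATOM %d %s %s . %s %s 1 %d %s %s %s 1.00 0.00 %s %s %s 1",
      seq_len(nrow(atm)), .elementOf(name), qname, comp, r$chain, r$seq,
      sprintf(fmt, atm$x), sprintf(fmt, atm$y), sprintf(fmt, atm$z),
      authSeq, authChain, comp))
  }
  out <- c(out, "#")
  writeLines(out, path)
  invisible(path)
}
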