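# Residue selection: resolve user-facing selectors (label or author
# numbering) against a loaded structure.

#' @keywords internal
.parseSelector <- function(sel) {
  # accepted forms: "B-57" (operator defaults to "1"), "B_2-57",
  # or list/vector (chain, seq) / (chain, operator, seq)
  if (is.character(sel) && length(sel) == 1L) {
    m <- regmatches(sel, regexec("^([^_-]+)(?:_([^-]+))?-(-?[0-9]+)$", sel))[[1L]]
    if (length(m) != 4L) stop("malformed selector: \"", sel, "\"")
    op <- if (m[3L] == "") "1" else m[3L]
    return(list(chain = m[2L], operator = op, seq = as.integer(m[4L]),
                label = sel))
  }
  sel <- as.list(sel)
  if (length(sel) == 2L)
    return(list(chain = as.character(sel[[1L]]), operator = "1",
                seq = as.integer(sel[[2L]]),
                label = paste(sel[[1L]], sel[[2L]], sep = "-")))
  if (length(sel) == 3L)
    return(list(chain = as.character(sel[[1L]]),
                operator = as.character(sel[[2L]]),
                seq = as.integer(sel[[3L]]),
                label = paste0(sel[[1L]], "_", sel[[2L]], "-", sel[[3L]])))
  stop("malformed selector of length ", length(sel))
}

#' Select residues from a structure
#'
#' Resolves selectors against a \linkS4class{PolymerStructure} and returns
#' the matching residue rows in selector order. Selectors may use label
#' numbering (label_asym_id / label_seq_id, the internal addressing) or
#' author numbering (auth_asym_id / auth_seq_id, as printed in most
#' publications); author selectors are translated to label numbering.
#'
#' @param structure A \linkS4class{PolymerStructure}.
#' @param selectors List of selectors; each either a string "B-57"
#'   ("chain-seq"; assembly operator defaults to "1"; "B_2-57" names
#'   operator "2") or a vector (chain, seq) / (chain, operator, seq).
#' @param numbering "label" (default) or "auth".
#' @return data.frame of residue rows (same columns as
#'   \code{residueTable}) in selector order.
#' @export
selectResidues <- function(structure, selectors, numbering = c("label", "auth")) {
  numbering <- match.arg(numbering)
  res <- structure@residues
  rows <- vapply(selectors, function(s) {
    p <- .parseSelector(s)
    hit <- if (numbering == "label") {
      which(res$chain == p$chain & res$operator == p$operator &
              res$seq == p$seq)
    } else {
      which(res$authChain == p$chain & res$operator == p$operator &
              res$authSeq == p$seq)
    }
    if (length(hit) == 0L)
      stop("unresolvable selector \"", p$label, "\" (", numbering,
           " numbering) in ", structure@structureId)
    if (length(hit) > 1L)
      stop("ambiguous selector \"", p$label, "\" in ", structure@structureId)
    hit
  }, 1L)
  out <- res[rows, , drop = FALSE]
  out$row <- rows
  rownames(out) <- NULL
  out
}
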