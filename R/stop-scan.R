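## GSPPP-anchored three-window stop-codon survey across genome collections.
##
## Windows, relative to the anchor glycine in its reading frame:
##   i   the 100 codons upstream of the glycine,
##   ii  the 100 codons from the glycine downstream (the gau sequence),
##   iii the next 100 codons (downstream of candidate stop codon 101).
## Window i records the LAST stop position (how close to the gau start the
## upstream frame is open), windows ii and iii the FIRST.

.WINDOWS <- c("i", "ii", "iii")

.decile <- function(pos) as.integer(ceiling(pos / 10) * 10L)

#' Scan one record for GSPPP-anchored stop-codon windows
#'
#' Finds the anchor motif across the six frames (minus frames preferred, as
#' in the gau geometry), then catalogues stop codons in the three 100-codon
#' windows around it under the record's genetic code.
#'
#' @param seq nucleotide string (a CDS or a genome).
#' @param code a \code{\linkS4class{GeneticCode}} for this record.
#' @param motif anchor motif (default \code{"GSPPP"}).
#' @param id,phylum labels carried into the output row.
#' @return one-row data.frame: \code{id}, \code{phylum},
#'   \code{anchor_found}, \code{frame}, \code{anchor_index}, and per window
#'   w in i/ii/iii: \code{w_n_stops}, \code{w_stops} (comma-joined 1-based
#'   positions within the window), \code{w_decile} (last-stop decile for i,
#'   first-stop decile for ii/iii; NA when stop-free), \code{w_no_stop},
#'   \code{w_covered} (FALSE when the window runs off the sequence; its
#'   stop fields are then NA).
#' @export
scanRecord <- function(seq, code, motif = "GSPPP", id = "record",
                       phylum = NA_character_) {
  s <- .normalizeSeq(seq)
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  hits <- findAnchor(s, code, motif)
  base <- data.frame(id = id, phylum = phylum, stringsAsFactors = FALSE)
  if (!nrow(hits)) {
    row <- cbind(base, anchor_found = FALSE, frame = NA_character_,
                 anchor_index = NA_integer_)
    for (w in .WINDOWS) {
      row[[paste0(w, "_n_stops")]] <- NA_integer_
      row[[paste0(w, "_stops")]] <- NA_character_
      row[[paste0(w, "_decile")]] <- NA_integer_
      row[[paste0(w, "_no_stop")]] <- NA
      row[[paste0(w, "_covered")]] <- FALSE
    }
    return(row)
  }
  anchor <- .primaryAnchor(hits)
  ft <- translateFrame(s, code, anchor$frame)
  L <- nchar(ft@protein)
  a <- anchor$codon_index
  starts <- c(i = a - 100L, ii = a, iii = a + 100L)
  row <- cbind(base, anchor_found = TRUE, frame = anchor$frame,
               anchor_index = as.integer(a))
  for (w in .WINDOWS) {
    s0 <- starts[[w]]
    covered <- s0 >= 1L && s0 + 99L <= L
    if (covered) {
      pos <- countStops(ft, s0, 100L)
      dec <- if (!length(pos)) NA_integer_
             else if (w == "i") .decile(max(pos)) else .decile(min(pos))
      row[[paste0(w, "_n_stops")]] <- length(pos)
      row[[paste0(w, "_stops")]] <- paste(pos, collapse = ",")
      row[[paste0(w, "_decile")]] <- dec
      row[[paste0(w, "_no_stop")]] <- !length(pos)
    } else {
      row[[paste0(w, "_n_stops")]] <- NA_integer_
      row[[paste0(w, "_stops")]] <- NA_character_
      row[[paste0(w, "_decile")]] <- NA_integer_
      row[[paste0(w, "_no_stop")]] <- NA
    }
    row[[paste0(w, "_covered")]] <- covered
  }
  row
}

#' Aggregate scan rows into a decile histogram table
#'
#' Per phylum and window: counts of sequences whose (first or last) stop
#' falls in each decile bin 10..100, the count of stop-free sequences, and
#' grand totals with/without stops. Rows without an anchor, or with an
#' uncovered window, are excluded from that window's tallies.
#'
#' @param rows data.frame of rows from \code{\link{scanRecord}}.
#' @return list with \code{histogram} (data.frame: \code{window},
#'   \code{phylum}, \code{d10}..\code{d100}, \code{no_stop}) and
#'   \code{totals} (data.frame: \code{window}, \code{with_stops},
#'   \code{without_stops}).
#' @export
aggregateScan <- function(rows) {
  if (!nrow(rows)) stop("no rows to aggregate")
  decLevels <- seq(10L, 100L, by = 10L)
  hist_ <- NULL; totals <- NULL
  for (w in .WINDOWS) {
    cov <- rows$anchor_found & rows[[paste0(w, "_covered")]] %in% TRUE
    sub <- rows[cov, , drop = FALSE]
    phyla <- unique(as.character(sub$phylum))
    for (ph in if (length(phyla)) phyla else character(0)) {
      ss <- sub[as.character(sub$phylum) %in% ph, , drop = FALSE]
      dec <- ss[[paste0(w, "_decile")]]
      cnt <- table(factor(dec, levels = decLevels))
      hist_ <- rbind(hist_, cbind(
        data.frame(window = w, phylum = ph, stringsAsFactors = FALSE),
        as.data.frame(t(as.integer(cnt))) |>
          stats::setNames(paste0("d", decLevels)),
        data.frame(no_stop = sum(ss[[paste0(w, "_no_stop")]]))))
    }
    totals <- rbind(totals, data.frame(
      window = w,
      with_stops = sum(!sub[[paste0(w, "_no_stop")]]),
      without_stops = sum(sub[[paste0(w, "_no_stop")]]),
      stringsAsFactors = FALSE))
  }
  list(histogram = hist_, totals = totals)
}
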