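# Plain-text interchange: long-format interval records (one row per
# animal x interval), a compact wide sequence format (one sequence per row,
# single-character states), and square distance matrices.

#' Read and write long-format interval records
#'
#' Tab-delimited text with a header row; columns as documented in
#' [build_state_sequence()] (`animal_id`, `group_id`, `interval_index`,
#' `instantaneous_state`, `locp_flag`, `socp_flag`, `toy_id`,
#' `objp_onset_kind`, `objp_company`).
#'
#' @param path File path.
#' @param records Data frame of interval records.
#' @return `read_records`: the records data frame; `write_records`: the
#'   path, invisibly.
#' @export
read_records <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("animal_id", "interval_index", "instantaneous_state",
              "locp_flag", "socp_flag")
  miss <- setdiff(needed, names(rec))
  if (length(miss))
    stop("records file lacks columns: ", paste(miss, collapse = ", "))
  rec$locp_flag <- as.logical(rec$locp_flag)
  rec$socp_flag <- as.logical(rec$socp_flag)
  rec
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

state_chars <- c(NoP = "N", ObjP = "O", LocSocP = "L")

#' Read and write sequences in compact wide format
#'
#' One sequence per row: `animal_id`, `group_id`, then the states as an
#' unbroken string of single characters (`N` = NoP, `O` = ObjP,
#' `L` = LocSocP, `-` = missing).
#'
#' @param seqs Named list of `state_sequence` objects.
#' @param path File path.
#' @return `read_wide`: a named list of `state_sequence` objects;
#'   `write_wide`: the path, invisibly.
#' @export
write_wide <- function(seqs, path) {
  rows <- vapply(seqs, function(s) {
    ch <- state_chars[s$states]
    ch[is.na(ch)] <- "-"
    paste(s$animal_id, s$group_id, paste(ch, collapse = ""), sep = "\t")
  }, character(1))
  writeLines(c("animal_id\tgroup_id\tstates", rows), path)
  invisible(path)
}

#' @rdname write_wide
#' @export
read_wide <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  inv <- setNames(names(state_chars), state_chars)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ch <- strsplit(tab$states[i], "")[[1L]]
    st <- unname(inv[ch])  # unknown chars (incl. "-") become NA
    structure(list(animal_id = tab$animal_id[i], group_id = tab$group_id[i],
                   states = st, covariates = list()),
              class = "state_sequence")
  })
  names(out) <- tab$animal_id
  out
}

#' Read and write a distance matrix as delimited text
#'
#' Square tab-delimited matrix with animal ids as header row and first
#' column.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param path File path.
#' @return `read_distances`: the matrix; `write_distances`: the path,
#'   invisibly.
#' @export
write_distances <- function(D, path) {
  write.table(as.matrix(D), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
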