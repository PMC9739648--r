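#' Parse and format transmit-set vectors
#'
#' A transmit set lists the activity classes for which a supporting node must
#' report its local classification result to the main node. It is written as
#' a bracketed 0/1 vector over the 8 classes in canonical order, e.g.
#' `"[1, 0, 0, 0, 1, 1, 1, 0]"` — a 1 at position `j` means the node transmits
#' whenever it recognises activity `j`.
#'
#' @param text A single string: a bracketed, comma-separated list of exactly
#'   eight 0/1 tokens. Brackets are optional.
#' @return `parse_transmit_vector()` returns a logical vector of length 8
#'   named by [activity_levels()].
#' @export
#' @examples
#' parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]")
#' format_transmit_vector(c(TRUE, rep(FALSE, 7)))
parse_transmit_vector <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    abort("`text` must be a single string.", class = "panhar_parse_error")
  }
  body <- gsub("^\\s*\\[|\\]\\s*$", "", trimws(text))
  tokens <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  n_classes <- length(activity_levels())
  if (length(tokens) != n_classes) {
    abort(sprintf("Expected %d comma-separated 0/1 tokens, found %d in \"%s\".",
                  n_classes, length(tokens), text),
          class = "panhar_parse_error")
  }
  bad <- which(!tokens %in% c("0", "1"))
  if (length(bad) > 0) {
    abort(sprintf("Token %d (\"%s\") is not 0 or 1 in \"%s\".",
                  bad[1], tokens[bad[1]], text),
          class = "panhar_parse_error")
  }
  setNames(tokens == "1", activity_levels())
}

#' @rdname parse_transmit_vector
#' @param flags Logical (or 0/1) vector of length 8 in canonical class order.
#' @return `format_transmit_vector()` returns the canonical bracketed string.
#' @export
format_transmit_vector <- function(flags) {
  flags <- check_flags(flags)
  paste0("[", paste(as.integer(flags), collapse = ", "), "]")
}

check_flags <- function(flags) {
  n_classes <- length(activity_levels())
  if (length(flags) != n_classes || anyNA(flags)) {
    abort(sprintf("A transmit set must be %d non-missing 0/1 flags.", n_classes),
          class = "panhar_bad_transmit_set")
  }
  if (!is.logical(flags)) {
    if (!all(flags %in% c(0, 1))) {
      abort("Transmit-set flags must be logical or 0/1.",
            class = "panhar_bad_transmit_set")
    }
    flags <- flags == 1
  }
  setNames(flags, activity_levels())
}

#' Read a transmit-set table
#'
#' Reads the plain-text format used to exchange per-configuration transmit
#' sets: one line per network configuration,
#' `main,supports,vector1;vector2;...`, where `supports` is a space-separated
#' list of node codes and each `vector` is a bracketed 0/1 vector (one per
#' supporting node, in the same order). Lines starting with `#` are comments.
#'
#' The package ships the published reference table of optimized transmit sets
#' for all 28 multi-node configurations at
#' `system.file("extdata", "transmit_sets.txt", package = "panhar")`.
#'
#' @param path Path to the file.
#' @return A tibble with one row per configuration: `main` (character),
#'   `supports` (list of character vectors) and `sets` (list of lists of
#'   named logical vectors, one per support).
#' @export
read_transmit_sets <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- map(lines, function(line) {
    m <- regmatches(line, regexec("^([^,]+),([^,\\[]*),(.*)$", line))[[1]]
    if (length(m) != 4L) {
      abort(paste0("Malformed transmit-set line: ", line),
            class = "panhar_parse_error")
    }
    supports <- strsplit(trimws(m[3]), "\\s+")[[1]]
    vectors <- strsplit(m[4], ";", fixed = TRUE)[[1]]
    if (length(vectors) != length(supports)) {
      abort(sprintf("Line \"%s\": %d supports but %d vectors.",
                    line, length(supports), length(vectors)),
            class = "panhar_parse_error")
    }
    tibble(main = trimws(m[2]),
           supports = list(supports),
           sets = list(setNames(map(vectors, parse_transmit_vector), supports)))
  })
  bind_rows(rows)
}

#' @rdname read_transmit_sets
#' @param table A tibble as returned by `read_transmit_sets()`.
#' @param path Output file path.
#' @export
write_transmit_sets <- function(table, path) {
  lines <- pmap(table, function(main, supports, sets) {
    paste0(main, ",", paste(supports, collapse = " "), ",",
           paste(map_chr(sets, format_transmit_vector), collapse = ";"))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Reference transmit-set table
#'
#' Convenience accessor for the packaged reference table of optimized
#' transmit sets (28 multi-node configurations over mounts s1--s4).
#'
#' @return A tibble, see [read_transmit_sets()].
#' @export
reference_transmit_sets <- function() {
  read_transmit_sets(system.file("extdata", "transmit_sets.txt",
                                 package = "panhar", mustWork = TRUE))
}
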