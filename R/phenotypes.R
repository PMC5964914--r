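#' Derive the binary traits P/NP and H/NH from horn scores
#'
#' The four-class horn score is collapsed into the two study traits:
#' polled/non-polled (`pnp`: polled = 0, every other score = 1) and
#' horned/non-horned (`hnh`: horned = 1, every other score = 0). Knobs and
#' scurs therefore count as non-polled but also non-horned, so `hnh <= pnp`
#' always holds. Labels are matched case-insensitively against the canonical
#' vocabulary `polled`, `knobs`, `scurs`, `horned`.
#'
#' @param horn_score character vector of horn scores.
#' @return data.frame with columns `pnp` and `hnh` (integer 0/1).
#' @export
derive_binary_traits <- function(horn_score) {
  hs <- tolower(as.character(horn_score))
  vocab <- c("polled", "knobs", "scurs", "horned")
  bad <- !is.na(hs) & !hs %in% vocab
  if (any(bad)) {
    stop("unknown horn score(s): ", paste(unique(horn_score[bad]), collapse = ", "),
         "; allowed: ", paste(vocab, collapse = ", "))
  }
  data.frame(pnp = as.integer(hs != "polled"),
             hnh = as.integer(hs == "horned"))
}

#' Construct a phenotype table
#'
#' @param animal animal identifiers.
#' @param horn_score four-class horn scores (see [derive_binary_traits()]).
#' @return data.frame of class `phenotypes` with columns `animal`,
#'   `horn_score` (canonical lower case), `pnp`, `hnh`.
#' @export
phenotype_table <- function(animal, horn_score) {
  animal <- as.character(animal)
  if (anyDuplicated(animal)) stop("duplicate animal ids in phenotypes")
  bt <- derive_binary_traits(horn_score)
  out <- data.frame(animal = animal, horn_score = tolower(as.character(horn_score)),
                    pnp = bt$pnp, hnh = bt$hnh, stringsAsFactors = FALSE)
  class(out) <- c("phenotypes", "data.frame")
  out
}

#' Read phenotypes from delimited text
#'
#' Expects a header with columns `animal,horn_score` (CSV or TSV).
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("animal", "horn_score") %in% names(d))) {
    stop("phenotype file must have columns: animal, horn_score")
  }
  phenotype_table(d$animal, d$horn_score)
}

#' Write phenotypes to CSV
#'
#' @param phe a [phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phe, path) {
  utils::write.csv(as.data.frame(phe), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
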