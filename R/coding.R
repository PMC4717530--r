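#' Code a tip state from per-niche locality counts
#'
#' Majority rule with a polymorphism threshold: the primary state is the
#' count argmax (ties include every tied state), and any further state
#' holding at least one third of the species' localities is added.
#'
#' @param counts numeric vector of length 3: localities in niches A, B, C.
#' @param threshold polymorphism fraction (default 1/3).
#' @return Character vector, a non-empty subset of c("A", "B", "C").
#' @export
code_tip_state <- function(counts, threshold = 1 / 3) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all-zero counts cannot be coded", call. = FALSE)
  states <- c("A", "B", "C")
  primary <- states[counts == max(counts)]
  extra <- states[counts / total >= threshold]
  sort(union(primary, extra))
}

#' Apply tip-state coding to a species count table
#'
#' Applies [code_tip_state()] per species; optional overrides replace the
#' rule output (marked `source = "override"`). A discrepancy report lists
#' every species whose rule-derived code differs from its override.
#'
#' @param counts data frame with columns `species`, `nA`, `nB`, `nC`
#'   (species unique).
#' @param overrides optional named list / character vector: species ->
#'   state string such as "AC" (or "A|C").
#' @param threshold polymorphism fraction for the rule.
#' @return An object of class `tip_state_coding`: data frame with
#'   `species`, `nA`, `nB`, `nC`, `states` (e.g. "A|C"), `source`;
#'   attribute `discrepancies` (data frame of rule/override conflicts).
#' @export
apply_coding <- function(counts, overrides = NULL, threshold = 1 / 3) {
  stopifnot(is.data.frame(counts),
            all(c("species", "nA", "nB", "nC") %in% names(counts)))
  if (anyDuplicated(counts$species)) stop("species must be unique",
                                          call. = FALSE)
  norm_states <- function(s) {
    paste(sort(unique(strsplit(gsub("[^ABC]", "", s), "")[[1]])),
          collapse = "|")
  }
  rule <- vapply(seq_len(nrow(counts)), function(i) {
    paste(code_tip_state(c(counts$nA[i], counts$nB[i], counts$nC[i]),
                         threshold), collapse = "|")
  }, character(1))
  states <- rule
  source <- rep("rule", nrow(counts))
  disc <- NULL
  if (!is.null(overrides)) {
    ov_names <- names(overrides)
    unknown <- setdiff(ov_names, counts$species)
    if (length(unknown)) {
      stop("override for unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (sp in ov_names) {
      i <- match(sp, counts$species)
      ov <- norm_states(overrides[[sp]])
      if (!nzchar(ov)) stop("empty override for ", sp, call. = FALSE)
      if (ov != rule[i]) {
        disc <- rbind(disc, data.frame(species = sp, rule = rule[i],
                                       override = ov))
      }
      states[i] <- ov
      source[i] <- "override"
    }
  }
  out <- data.frame(species = counts$species, nA = counts$nA,
                    nB = counts$nB, nC = counts$nC, states = states,
                    source = source, stringsAsFactors = FALSE)
  attr(out, "discrepancies") <-
    if (is.null(disc)) data.frame(species = character(),
                                  rule = character(),
                                  override = character()) else disc
  class(out) <- c("tip_state_coding", "data.frame")
  out
}

#' Niche-state frequency accounting
#'
#' Each species contributes `1 / (number of coded states)` to each of its
#' states, so the frequencies sum to the species count.
#'
#' @param coding a [apply_coding()] result, or a data frame with a
#'   `states` column of "|"-separated state strings.
#' @return Named numeric vector of frequencies over A, B, C.
#' @export
state_frequencies <- function(coding) {
  sets <- strsplit(coding$states, "|", fixed = TRUE)
  if (!length(sets)) stop("need at least one species", call. = FALSE)
  freq <- c(A = 0, B = 0, C = 0)
  for (s in sets) freq[s] <- freq[s] + 1 / length(s)
  freq
}

#' Published locality-count table for the Madagascan Bulbophyllum study
#' clade
#'
#' Per-species counts of georeferenced localities falling in each of the
#' three macroecological niches (A, B, C) for the 33 species of the
#' study clade (30 ingroup plus 3 outgroups), together with the published
#' niche-state codes. Two digit-grouped rows of the printed table are
#' ambiguous; this transcription adopts the reading that reproduces the
#' published row totals (604 records) and column sums, as flagged in the
#' CSV header comments.
#'
#' @return `clade_c_counts()`: data frame `species`, `section`, `nA`,
#'   `nB`, `nC`; `clade_c_codes()`: named character vector of published
#'   codes.
#' @export
clade_c_counts <- function() {
  path <- system.file("extdata", "clade_c_niche_counts.csv",
                      package = "phyloniche", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname clade_c_counts
#' @export
clade_c_codes <- function() {
  path <- system.file("extdata", "clade_c_niche_codes.csv",
                      package = "phyloniche", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(df$states, df$species)
}

#' The packaged coding of the study clade
#'
#' Convenience wrapper: [apply_coding()] on the packaged counts with the
#' published codes as overrides (the published Coding column is
#' authoritative for downstream model comparison).
#'
#' @return A `tip_state_coding`.
#' @export
clade_c_coding <- function() {
  apply_coding(clade_c_counts(), clade_c_codes())
}
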