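# Pattern-state coding, character tables, and clade-level tabulation.

parse_motifs <- function(x) {
  if (length(x) == 1 && is.character(x)) {
    m <- toupper(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
    m <- m[nzchar(m)]
  } else {
    m <- toupper(trimws(as.character(x)))
  }
  if (length(m) == 0) m <- "NONE"
  unique(m)
}

validate_motifs <- function(motifs, taxon = NULL, sex = NULL) {
  bad <- setdiff(motifs, ALL_MOTIFS)
  if (length(bad) > 0) {
    where <- if (!is.null(taxon)) sprintf(" for taxon '%s' (%s)", taxon, sex) else ""
    stop(sprintf("invalid motif code%s: %s (valid: %s)", where,
                 paste(bad, collapse = ", "), paste(ALL_MOTIFS, collapse = ", ")),
         call. = FALSE)
  }
  if ("NONE" %in% motifs && length(motifs) > 1) {
    where <- if (!is.null(taxon)) sprintf(" for taxon '%s' (%s)", taxon, sex) else ""
    stop(sprintf("motif NONE cannot co-occur with other motifs%s", where),
         call. = FALSE)
  }
  motifs
}

# pattern components present in one sex's motif set: "irregular", "regular"
sex_components <- function(motifs) {
  comp <- character(0)
  if (any(motifs %in% IRREGULAR_MOTIFS)) comp <- c(comp, "irregular")
  if (any(motifs %in% REGULAR_MOTIFS)) comp <- c(comp, "regular")
  comp
}

# within-sex phenotype: "none", "irregular", "regular" or "bimodal"
sex_phenotype <- function(motifs) {
  comp <- sex_components(motifs)
  if (length(comp) == 0) return("none")
  if (length(comp) == 2) return("bimodal")
  comp
}

#' Classify a species' pattern state from per-sex motif codes
#'
#' Mottling (and other irregular motifs) contributes an irregular component;
#' bars, scales and spots (and other regular motifs) contribute a regular
#' component. The union of components over both sexes determines the state:
#' both components present (within one sex or across sexes) gives bimodal,
#' only regular gives regular, only irregular gives irregular, and neither
#' gives uniform. A species in which only one sex is patterned is classified
#' by that sex's patterns. The classification is symmetric in its two
#' arguments.
#'
#' @param male,female Motif codes for each sex: a character vector of motifs
#'   or a single semicolon-separated string. Valid motifs are `NONE`,
#'   `MOTTLE`, `OTHER_IRREGULAR`, `BAR`, `SCALE`, `SPOT`, `OTHER_REGULAR`;
#'   `NONE` cannot co-occur with any other motif.
#' @param taxon Optional taxon label used in error messages.
#' @return One of `"uniform"`, `"irregular"`, `"regular"`, `"bimodal"`.
#' @export
#' @examples
#' classify_species("NONE", "NONE")
#' classify_species("BAR", "MOTTLE")
#' classify_species("SPOT", "NONE")
#' classify_species("MOTTLE;BAR", "NONE")
classify_species <- function(male, female, taxon = NULL) {
  m <- validate_motifs(parse_motifs(male), taxon, "male")
  f <- validate_motifs(parse_motifs(female), taxon, "female")
  comp <- union(sex_components(m), sex_components(f))
  if (length(comp) == 2) return("bimodal")
  if (length(comp) == 0) return("uniform")
  comp
}

new_pattern_characters <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("pattern_characters", "data.frame")
  df
}

#' Build a pattern character table from per-sex motif codes
#'
#' @param taxon Character vector of unique taxon labels.
#' @param male,female Character vectors of semicolon-separated motif codes,
#'   one entry per taxon (see [classify_species()]).
#' @param state Optional pre-assigned states; when supplied they are
#'   validated against the classification derived from the motif codes.
#' @return A `pattern_characters` data frame with columns `taxon`, `male`,
#'   `female`, `state`.
#' @export
pattern_characters <- function(taxon, male = NULL, female = NULL, state = NULL) {
  taxon <- as.character(taxon)
  if (anyDuplicated(taxon))
    stop("duplicate taxon labels: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  n <- length(taxon)
  if (is.null(male) && is.null(female)) {
    if (is.null(state)) stop("supply either per-sex motif codes or states")
    state <- match.arg(as.character(state), PATTERN_STATES, several.ok = TRUE)
    if (length(state) != n) stop("state must have one entry per taxon")
    return(new_pattern_characters(data.frame(
      taxon = taxon, male = NA_character_, female = NA_character_,
      state = state, stringsAsFactors = FALSE)))
  }
  male <- as.character(male)
  female <- as.character(female)
  if (length(male) != n || length(female) != n)
    stop("male and female must have one entry per taxon")
  derived <- vapply(seq_len(n), function(i)
    classify_species(male[i], female[i], taxon = taxon[i]), character(1))
  if (!is.null(state)) {
    state <- as.character(state)
    bad <- which(state != derived)
    if (length(bad) > 0)
      stop("stated pattern state disagrees with motif classification for: ",
           paste(sprintf("%s (stated %s, derived %s)", taxon[bad],
                         state[bad], derived[bad]), collapse = "; "))
  }
  new_pattern_characters(data.frame(
    taxon = taxon, male = male, female = female, state = derived,
    stringsAsFactors = FALSE))
}

#' Read a pattern character table from CSV
#'
#' Expected columns: `taxon`, `male_motifs`, `female_motifs` (semicolon
#' separated motif codes) and optionally `state`, which is validated against
#' the classification derived from the motifs. Alternatively a file with
#' just `taxon` and `state` columns is accepted (no per-sex information).
#'
#' @param path Path to a CSV file.
#' @return A `pattern_characters` data frame.
#' @export
read_characters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(df)) stop("character CSV needs a 'taxon' column")
  if (nrow(df) == 0) stop("character table is empty: ", path)
  if (all(c("male_motifs", "female_motifs") %in% names(df))) {
    pattern_characters(df$taxon, df$male_motifs, df$female_motifs,
                       state = if ("state" %in% names(df)) df$state)
  } else if ("state" %in% names(df)) {
    pattern_characters(df$taxon, state = df$state)
  } else {
    stop("character CSV needs 'male_motifs'/'female_motifs' or 'state' columns")
  }
}

#' Write a pattern character table to CSV
#'
#' Inverse of [read_characters()]: reading the written file reproduces the
#' same records.
#'
#' @param x A `pattern_characters` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_characters <- function(x, path) {
  stopifnot(inherits(x, "pattern_characters"))
  out <- data.frame(taxon = x$taxon, male_motifs = x$male,
                    female_motifs = x$female, state = x$state,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write pattern states as a NEXUS data block
#'
#' States are encoded with the 4-symbol alphabet 0 = uniform, 1 = irregular,
#' 2 = regular, 3 = bimodal. Per-sex motif codes are not representable in
#' this encoding.
#'
#' @param path Path to a NEXUS file.
#' @return For `read_characters_nexus`, a `pattern_characters` data frame.
#' @export
read_characters_nexus <- function(path) {
  dat <- ape::read.nexus.data(path)
  sym <- vapply(dat, function(x) as.character(x[1]), character(1))
  idx <- match(sym, as.character(0:3))
  if (anyNA(idx))
    stop("NEXUS symbols outside the 0-3 pattern alphabet: ",
         paste(unique(sym[is.na(idx)]), collapse = ", "))
  pattern_characters(names(dat), state = PATTERN_STATES[idx])
}

#' @rdname read_characters_nexus
#' @param x A `pattern_characters` data frame.
#' @export
write_characters_nexus <- function(x, path) {
  stopifnot(inherits(x, "pattern_characters"))
  idx <- match(x$state, PATTERN_STATES) - 1L
  dat <- lapply(idx, as.character)
  names(dat) <- x$taxon
  ape::write.nexus.data(dat, path, format = "standard")
  invisible(path)
}

#' Read a clade map from CSV
#'
#' @param path CSV with columns `taxon`, `order`, `subfamily`, `tribe`.
#'   Empty strings mark unassigned levels.
#' @return A data frame with those four columns.
#' @export
read_clade_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "order", "subfamily", "tribe")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clade map is missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Tabulate pattern-type frequencies by clade
#'
#' For each clade at the requested level, reports the percentage of species
#' in each pattern state (percentages kept at full precision; the print
#' method rounds to whole percent and renders zeros as a dash, the
#' convention used for clade frequency tables in the comparative
#' literature).
#'
#' @param x A `pattern_characters` data frame.
#' @param clade_map Data frame mapping `taxon` to `order`, `subfamily`,
#'   `tribe` (see [read_clade_map()]); may be `NULL` for a single overall
#'   row.
#' @param level One of `"order"`, `"subfamily"`, `"tribe"`.
#' @return A `pattern_freq_table` data frame with columns `clade`,
#'   `n_species` and one percentage column per pattern state.
#' @export
tabulate_frequencies <- function(x, clade_map = NULL,
                                 level = c("order", "subfamily", "tribe")) {
  stopifnot(inherits(x, "pattern_characters"))
  level <- match.arg(level)
  if (nrow(x) == 0) stop("empty character matrix")
  if (is.null(clade_map)) {
    clade <- rep("(all)", nrow(x))
  } else {
    i <- match(x$taxon, clade_map$taxon)
    unassigned <- x$taxon[is.na(i)]
    if (length(unassigned) > 0)
      warning("taxa absent from the clade map are excluded from ",
              "clade rows: ", paste(unassigned, collapse = ", "))
    clade <- clade_map[[level]][i]
    clade[!is.na(clade) & clade == ""] <- NA
    if (level == "order") {
      # order level keeps every record; unassigned taxa are folded into the
      # single order when it is unambiguous
      orders <- stats::na.omit(unique(clade))
      clade[is.na(clade)] <- if (length(orders) == 1) orders else "(unassigned)"
    }
    keep <- !is.na(clade)
    x <- x[keep, , drop = FALSE]
    clade <- clade[keep]
    if (nrow(x) == 0) stop("no taxa assigned at level '", level, "'")
  }
  clades <- unique(clade)
  rows <- lapply(clades, function(cl) {
    st <- x$state[clade == cl]
    n <- length(st)
    pct <- 100 * vapply(PATTERN_STATES, function(s) sum(st == s), numeric(1)) / n
    c(n_species = n, pct)
  })
  out <- data.frame(clade = clades, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pattern_freq_table", "data.frame")
  out
}

#' @export
print.pattern_freq_table <- function(x, ...) {
  disp <- x
  for (s in PATTERN_STATES) {
    v <- round(disp[[s]])
    disp[[s]] <- ifelse(v == 0, "–", as.character(v))
  }
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Breakdown of bimodal species by sex phenotype
#'
#' Among species classified bimodal overall, returns the proportions of
#' (a) species in which both sexes are individually bimodal, (b) species in
#' which exactly one sex is individually bimodal (the other being singularly
#' patterned or unpatterned), and (c) species in which one sex is regular
#' and the other irregular. The three proportions partition the bimodal
#' species and sum to one.
#'
#' @param x A `pattern_characters` data frame with per-sex motif codes.
#' @return Named numeric vector `c(both_bimodal, one_bimodal, across_sexes)`.
#' @export
bimodal_sex_breakdown <- function(x) {
  stopifnot(inherits(x, "pattern_characters"))
  b <- x[x$state == "bimodal", , drop = FALSE]
  if (nrow(b) == 0) stop("no bimodal species in the character table")
  if (anyNA(b$male) || anyNA(b$female))
    stop("per-sex motif codes are required for the bimodal breakdown")
  ph_m <- vapply(b$male, function(m) sex_phenotype(parse_motifs(m)), character(1))
  ph_f <- vapply(b$female, function(m) sex_phenotype(parse_motifs(m)), character(1))
  nb <- (ph_m == "bimodal") + (ph_f == "bimodal")
  out <- c(both_bimodal = mean(nb == 2),
           one_bimodal = mean(nb == 1),
           across_sexes = mean(nb == 0))
  out
}
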