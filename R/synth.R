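# Synthetic datasets with planted homologous families, decoys, duplicates
# and hypothetical-protein records, so every pipeline stage is testable
# without any download.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_residues <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

# Per-site i.i.d. substitutions (uniform over the 19 alternatives) and
# per-site indels: with probability indel_rate a site hosts an event,
# insertion or deletion with equal probability, of length 1 + Geom(0.5)
# (mean 2).
mutate_sequence <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sub_hit <- stats::runif(n) < sub_rate
  for (i in which(sub_hit)) {
    chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  }
  if (indel_rate > 0) {
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < indel_rate) {
        len <- 1L + stats::rgeom(1, 0.5)
        if (stats::runif(1) < 0.5) {
          out <- c(out, sample(AA_STANDARD, len, replace = TRUE), chars[i])
          i <- i + 1L
        } else {
          i <- i + len  # deletion removes len sites starting here
        }
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    chars <- out
  }
  if (length(chars) == 0L) chars <- sample(AA_STANDARD, 1L)
  paste(chars, collapse = "")
}

#' Specification of a planted homologous family
#'
#' Members are generated as independent mutants of one random seed
#' sequence. For the default clustering threshold of 0.8, substitution
#' rates up to ~0.15 and indel rates up to ~0.02 keep within-family
#' alignment-length ratios safely above the threshold.
#'
#' @param n_members Number of members (>= 1).
#' @param seed_length Length of the random seed sequence, in residues.
#' @param sub_rate Per-site substitution probability in [0, 1).
#' @param indel_rate Per-site indel probability in [0, 1).
#' @param rng_seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_members = 5L, seed_length = 120L, sub_rate = 0.05,
                        indel_rate = 0.01, rng_seed = 1L) {
  stopifnot(seed_length >= 1, sub_rate >= 0, sub_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  if (n_members < 1L) stop("n_members must be at least 1")
  structure(list(n_members = as.integer(n_members),
                 seed_length = as.integer(seed_length),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

#' Generate one planted homologous family
#'
#' Draws a random seed sequence uniformly over the 20 standard residues,
#' then emits `n_members` descendants by independent per-site substitution
#' and geometric-length indels. Byte-identical output for the same
#' `rng_seed`.
#'
#' @param spec A [family_spec()].
#' @param family_index Index used in accessions/annotations (default 1).
#' @return List with `records` (a record `data.frame`) and `truth`
#'   (data frame `seq_id`, `family`).
#' @export
make_family <- function(spec, family_index = 1L) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$rng_seed, {
    seed_seq <- random_residues(spec$seed_length)
    res <- vapply(seq_len(spec$n_members), function(m) {
      mutate_sequence(seed_seq, spec$sub_rate, spec$indel_rate)
    }, "")
    acc <- sprintf("SYN%03d_%03d.1", family_index, seq_len(spec$n_members))
    records <- seq_records(acc, res,
                           annotation = sprintf("synthetic family %d protein",
                                                family_index))
    list(records = records,
         truth = data.frame(seq_id = records$seq_id,
                            family = as.character(family_index),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a full synthetic dataset
#'
#' Concatenates `n_families` planted families, unrelated random decoys
#' (length-matched to the family seed length so that the length-ratio
#' statistic, not mere length, separates them), exact duplicates of
#' randomly chosen members, and records annotated as hypothetical
#' proteins, then shuffles the rows deterministically. The truth table
#' labels every record with its family index, `"decoy"`, `"duplicate"` or
#' `"hypothetical"`.
#'
#' @param n_families Number of planted families.
#' @param family A [family_spec()] used for every family (each family gets
#'   a derived sub-seed).
#' @param n_decoys Number of unrelated random sequences.
#' @param n_duplicates Number of exact duplicate records to add.
#' @param n_hypotheticals Number of hypothetical-protein records to add.
#' @param rng_seed Integer master seed.
#' @return List with `records` and `truth` (data frame `seq_id`,
#'   `family`).
#' @export
make_dataset <- function(n_families = 10L, family = family_spec(),
                         n_decoys = 2L, n_duplicates = 0L,
                         n_hypotheticals = 0L, rng_seed = 1L) {
  stopifnot(n_families >= 0, n_decoys >= 0, n_duplicates >= 0,
            n_hypotheticals >= 0)
  records <- seq_records(character(), character())
  truth <- data.frame(seq_id = character(), family = character(),
                      stringsAsFactors = FALSE)
  for (f in seq_len(n_families)) {
    fspec <- family
    fspec$rng_seed <- as.integer((as.numeric(rng_seed) * 1009 + f) %% 2147483629)
    fam <- make_family(fspec, family_index = f)
    records <- rbind(records, fam$records)
    truth <- rbind(truth, fam$truth)
  }
  with_seed(as.integer((as.numeric(rng_seed) * 7919 + 13) %% 2147483629), {
    if (n_decoys > 0) {
      dec <- seq_records(sprintf("DEC%03d.1", seq_len(n_decoys)),
                         vapply(seq_len(n_decoys), function(i)
                           random_residues(family$seed_length), ""),
                         annotation = "synthetic decoy protein")
      records <- rbind(records, dec)
      truth <- rbind(truth, data.frame(seq_id = dec$seq_id, family = "decoy",
                                       stringsAsFactors = FALSE))
    }
    if (n_duplicates > 0) {
      if (nrow(records) == 0L) stop("cannot duplicate from an empty dataset")
      src <- sample(nrow(records), n_duplicates, replace = TRUE)
      dup <- seq_records(sprintf("DUP%03d.1", seq_len(n_duplicates)),
                         records$residues[src],
                         annotation = paste("synthetic duplicate of",
                                            records$accession[src]))
      records <- rbind(records, dup)
      truth <- rbind(truth, data.frame(seq_id = dup$seq_id,
                                       family = "duplicate",
                                       stringsAsFactors = FALSE))
    }
    if (n_hypotheticals > 0) {
      hyp <- seq_records(sprintf("HYP%03d.1", seq_len(n_hypotheticals)),
                         vapply(seq_len(n_hypotheticals), function(i)
                           random_residues(family$seed_length), ""),
                         annotation = "hypothetical protein")
      records <- rbind(records, hyp)
      truth <- rbind(truth, data.frame(seq_id = hyp$seq_id,
                                       family = "hypothetical",
                                       stringsAsFactors = FALSE))
    }
    ord <- sample(nrow(records))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    truth <- truth[match(records$seq_id, truth$seq_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}
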