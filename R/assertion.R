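## Rule-based tagging of the "state" data property (positive/negative) for
## disease and clinical-finding mentions. Tumor records use fixed syntax: a
## negated finding follows one of a small set of cues (无明显/没有/未见/不伴,
## and bare 无 as in admission narratives); every other disease/finding
## mention is positive.

.STATEFUL_TYPES <- c("disease", "clinical finding", "symptom", "sign")
.HARD_BOUNDARIES <- c("。", "！", "？", "；", ";", "\n") # 。！？；;
.COMMA_CHARS <- c("，", ",") # ，,

#' Default negation cue list
#'
#' The four printed cues plus bare `无` (admission narratives negate with a
#' bare `无`, e.g. `无阵发性加剧`); pass only the first four to
#' [tag_states()] for the strict reading.
#' @return Character vector of cues.
#' @export
default_negation_cues <- function() .DEFAULT_CUES

#' Assign positive/negative states to disease and clinical-finding mentions
#'
#' A disease/clinical-finding mention is negative iff a cue occurs before it
#' in the same clause, with no intervening hard clause boundary
#' (`。！？；;`). A cue's scope extends across commas while each subsequent
#' clause consists only of disease/finding mentions plus closed-class filler
#' (`等`, `及`, `和`, whitespace), reproducing the enumeration reading of
#' `不伴恶心, 呕吐, 返酸, 嗳气等`. All remaining disease/finding mentions
#' are positive; other span types are untouched. Deterministic and
#' idempotent.
#'
#' @param text Document text.
#' @param mentions data.frame with 0-based half-open `start`, `end` and
#'   `sem_type` columns, sorted by `start` (a `state` column is added or
#'   overwritten for stateful types).
#' @param cues Character vector of negation cues.
#' @return `mentions` with the `state` column filled in.
#' @export
tag_states <- function(text, mentions, cues = default_negation_cues()) {
  n <- nchar(text)
  if (!nrow(mentions)) return(mentions)
  if (is.unsorted(mentions$start)) stopf("mentions must be sorted by start offset")
  if (any(mentions$start < 0) || any(mentions$end > n) || any(mentions$end <= mentions$start))
    stopf("mention offsets outside text")
  if (is.null(mentions$state)) mentions$state <- "not-applicable"
  stateful <- mentions$sem_type %in% .STATEFUL_TYPES
  mentions$state[stateful] <- "positive"

  cs <- chars(text)
  ## character classes for the scope-extension rule
  covered <- rep(FALSE, n) # inside a stateful mention
  for (i in which(stateful)) covered[(mentions$start[i] + 1L):mentions$end[i]] <- TRUE
  in_mention <- rep(FALSE, n) # inside any mention (cues there don't count)
  for (i in seq_len(nrow(mentions))) in_mention[(mentions$start[i] + 1L):mentions$end[i]] <- TRUE
  filler <- cs %in% .FILLER_CHARS
  hard <- cs %in% .HARD_BOUNDARIES
  comma <- cs %in% .COMMA_CHARS

  ## locate cue occurrences (0-based end position of each cue)
  cue_ends <- integer()
  for (cue in cues) {
    hits <- gregexpr(cue, text, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      if (!any(in_mention[h:(h + nchar(cue) - 1L)]))
        cue_ends <- c(cue_ends, h - 1L + nchar(cue))
    }
  }

  negate <- rep(FALSE, n)
  for (ce in sort(unique(cue_ends))) {
    pos <- ce + 1L # 1-based scan position
    repeat {
      ## current clause: up to the next boundary (hard or comma)
      clause_start <- pos
      while (pos <= n && !hard[pos] && !comma[pos]) pos <- pos + 1L
      if (pos > clause_start) negate[clause_start:(pos - 1L)] <- TRUE
      if (pos > n || hard[pos]) break
      ## comma: extend scope only over enumeration clauses (mentions+filler)
      nxt <- pos + 1L
      while (nxt <= n && !hard[nxt] && !comma[nxt]) nxt <- nxt + 1L
      clause <- if (nxt > pos + 1L) (pos + 1L):(nxt - 1L) else integer()
      if (!length(clause) || !all(covered[clause] | filler[clause])) break
      pos <- pos + 1L
    }
  }

  for (i in which(stateful)) {
    span <- (mentions$start[i] + 1L):mentions$end[i]
    if (all(negate[span])) mentions$state[i] <- "negative"
  }
  mentions
}
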