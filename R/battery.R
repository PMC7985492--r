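#' The default 52-test neuropsychological battery
#'
#' Metadata for the battery analysed throughout the package: 52 tests grouped
#' into five classical neuropsychological functions with per-function counts
#' 8 (receptive), 15 (expressive), 9 (attention/memory), 13 (processing) and
#' 7 (executive). Each test carries the maximum attainable raw score used by
#' [normalizeScores()].
#'
#' Test names follow the domain structure of the battery (visual/auditory/
#' haptic perception and receptive language; motor, praxic, constructional,
#' graphic and expressive-language skills; coding, recall and attention;
#' reasoning, math and pre-reading; flexibility, self-regulation, working
#' memory and theory of mind).
#'
#' @return A [S4Vectors::DataFrame] with columns `test_id` (1-52), `name`,
#'   `fn` (factor with levels `receptive`, `expressive`, `attention_memory`,
#'   `processing`, `executive`) and `max_raw` (positive integer).
#' @examples
#' bat <- defaultBattery()
#' table(bat$fn)
#' @export
defaultBattery <- function() {
  names <- c(
    # receptive (1-8): visual, auditory, haptic perception; receptive language
    "Visual figure discrimination",        # 1
    "Auditory tone discrimination",        # 2
    "Visual object recognition",           # 3
    "Haptic object recognition",           # 4
    "Left hand recognition",               # 5
    "Phoneme discrimination",              # 6
    "Following oral instructions",         # 7
    "Receptive vocabulary",                # 8
    # expressive (9-23): fine/gross motor, praxis, construction, graphic,
    # expressive language
    "Fine motor coordination",             # 9
    "Finger tapping sequence",             # 10
    "Block construction",                  # 11
    "Figure copying",                      # 12
    "Drawing a person",                    # 13
    "Ideomotor praxis",                    # 14
    "Gross motor balance",                 # 15
    "Ball throwing and catching",          # 16
    "Articulation of words",               # 17
    "Sentence repetition",                 # 18
    "Naming objects",                      # 19
    "Story retelling",                     # 20
    "Naming body parts",                   # 21
    "Verbal fluency",                      # 22
    "Describing a scene",                  # 23
    # attention/memory (24-32): coding, delayed recall, attention
    "Digit span forward",                  # 24
    "Word list learning",                  # 25
    "Delayed word recall",                 # 26
    "Sentence memory",                     # 27
    "Visual memory for designs",           # 28
    "Delayed design recall",               # 29
    "Sustained visual attention",          # 30
    "Auditory attention span",             # 31
    "Cancellation search",                 # 32
    # processing (33-45): reasoning, math, pre-reading
    "Picture analogies",                   # 33
    "Matrix reasoning",                    # 34
    "Classification of objects",           # 35
    "Serial ordering",                     # 36
    "Conservation of quantity",            # 37
    "Counting objects",                    # 38
    "Number comparison",                   # 39
    "Simple addition with objects",        # 40
    "Letter recognition",                  # 41
    "Rhyme detection",                     # 42
    "Syllable segmentation",               # 43
    "Print concept knowledge",             # 44
    "Visual-spatial puzzles",              # 45
    # executive (46-52): flexibility, self-regulation, working memory, ToM
    "Cognitive flexibility shifting",      # 46
    "Card sorting",                        # 47
    "Inhibitory control (day/night)",      # 48
    "Delay of gratification",              # 49
    "Self-regulation during play",         # 50
    "Working memory span (backward)",      # 51
    "Theory of mind (false belief)"        # 52
  )
  fn <- factor(
    rep(npFunctions(), times = c(8L, 15L, 9L, 13L, 7L)),
    levels = npFunctions()
  )
  DataFrame(
    test_id = 1:52,
    name = names,
    fn = fn,
    max_raw = rep(c(10L, 12L, 8L, 15L, 20L), length.out = 52L)
  )
}

#' The five neuropsychological function labels
#'
#' @return Character vector of the five function labels in battery order.
#' @export
npFunctions <- function() {
  c("receptive", "expressive", "attention_memory", "processing", "executive")
}

# Validate a battery table; returns it invisibly.
checkBattery <- function(battery) {
  need <- c("test_id", "name", "fn", "max_raw")
  if (!all(need %in% colnames(battery))) {
    stop("battery must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(battery$test_id)) stop("battery test_ids must be unique")
  if (!all(diff(sort(battery$test_id)) == 1L)) {
    stop("battery test_ids must be consecutive")
  }
  if (any(battery$max_raw <= 0)) stop("battery max_raw must be positive")
  invisible(battery)
}
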