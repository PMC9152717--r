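# Independent oracles the implementation is checked against. These are
# deliberately written from the textbook definitions, not by calling the
# package (or the base R helpers the package itself uses).

# Holm step-down, written out longhand
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    cand <- (m - i + 1) * p[ord[i]]
    running <- max(running, cand)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Welch two-sample t from the formulas
welch_oracle <- function(x, y, conf = 0.95) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  half <- qt(1 - (1 - conf) / 2, df) * sqrt(se2)
  list(t = t, df = df, p = p,
       ci = c(mean(x) - mean(y) - half, mean(x) - mean(y) + half))
}

# one-sample upper-tail t from the formulas
one_sample_oracle <- function(x, mu0) {
  n <- length(x)
  t <- (mean(x) - mu0) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = pt(t, n - 1, lower.tail = FALSE))
}

# gold word lists with hand-assigned syllable counts
gold_en <- c(
  cat = 1, dog = 1, go = 1, a = 1, sky = 1, heart = 1, blood = 1, skin = 1,
  brain = 1, pain = 1, bone = 1, nurse = 1, cough = 1, made = 1, makes = 1,
  walked = 1, lungs = 1, joint = 1,
  water = 2, fever = 2, chronic = 2, patient = 2, virus = 2, body = 2,
  pressure = 2, muscle = 2, table = 2, simple = 2, apple = 2, wanted = 2,
  houses = 2, cancer = 2, tumor = 2, kidney = 2, liver = 2, severe = 2,
  acute = 2, doctor = 2, treatment = 2, vaccine = 2, illness = 2,
  disease = 2, syndrome = 2,
  hospital = 3, medicine = 3, infection = 3, oxygen = 3, therapy = 3,
  readability = 5
)

gold_de <- c(
  Arzt = 1, Haus = 1, Herz = 1, Schmerz = 1, Blut = 1, Haut = 1, Ohr = 1,
  Darm = 1,
  Krankheit = 2, Fieber = 2, Husten = 2, Wasser = 2, Leber = 2, Niere = 2,
  Lunge = 2, Knochen = 2, Gehirn = 2, Impfung = 2, Auge = 2, Magen = 2,
  Zelle = 2, "Körper" = 2, Symptom = 2,
  Medizin = 3, Therapie = 3, Behandlung = 3, "Müdigkeit" = 3,
  "Übelkeit" = 3, "Entzündung" = 3
)

gold_ru <- c(
  "кашель" = 2, "болезнь" = 2, "сердце" = 2, "голова" = 3,
  "температура" = 5, "врач" = 1, "грипп" = 1, "печень" = 2, "почка" = 2,
  "лёгкие" = 3
)

# independent Russian vowel counter (base R, not stringr)
ru_vowel_oracle <- function(words) {
  vapply(tolower(words), function(w) {
    max(1L, sum(strsplit(w, "")[[1]] %in%
                  c("а", "е", "ё", "и", "о", "у", "ы", "э", "ю", "я")))
  }, integer(1), USE.NAMES = FALSE)
}

# constructed text: k sentences, m words each, s syllables per word;
# returns text with exactly known statistics
make_constructed_text <- function(lang, k, m, s) {
  sents <- vapply(seq_len(k), function(i) {
    w <- wikiread::generate_word(lang, rep(s, m))
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
  paste(sents, collapse = " ")
}

# small snapshot spec used across integration tests (fast)
small_spec <- function(seed = 101, ...) {
  wikiread::corpus_spec(
    n_clusters = 60,
    sentences_meanlog = c(en = 2.4, de = 2.4, ru = 2.4),
    sentences_sdlog = c(en = 0.4, de = 0.4, ru = 0.4),
    seed = seed,
    ...
  )
}
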