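# Shared fixtures and independent oracles for the test suite.

# A tiny valid replicate-level table: 3 regions x 2 replicates, 2 variables.
tiny_table <- function() {
  measurement_table(data.frame(
    sample_id = paste0("S", 1:6),
    region = rep(c("M1", "M2", "M3"), each = 2),
    species = "toringoides",
    x = c(1, 2, 3, 4, 5, 6),
    y = c(2, 2, 4, 4, 9, 9)),
    units = c(x = "g/kg", y = "%"))
}

# Independent brute-force oracle for Duncan's multiple range test: applies
# the R_p rule to every span directly, then propagates containment to a
# fixpoint (a sub-range of a non-significant range is non-significant).
# Returns list(order, nonsig) with nonsig a logical matrix over the means
# sorted in descending order (TRUE = not significantly different).
oracle_duncan <- function(means, ns, mse, df, alpha = 0.05) {
  ord <- order(-means, names(means))
  m <- unname(means[ord])
  nn <- unname(ns[ord])
  k <- length(m)
  nonsig <- diag(TRUE, k)
  if (k >= 2) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        p <- j - i + 1
        alpha_p <- 1 - (1 - alpha)^(p - 1)
        n_h <- 2 / (1 / nn[i] + 1 / nn[j])
        rp <- qtukey(1 - alpha_p, nmeans = p, df = df) * sqrt(mse / n_h)
        nonsig[i, j] <- nonsig[j, i] <- abs(m[i] - m[j]) <= rp
      }
    }
    repeat {
      changed <- FALSE
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        if (!nonsig[i, j]) {
          for (a in 1:i) for (b in j:k) {
            if (!(a == i && b == j) && nonsig[a, b]) {
              nonsig[i, j] <- nonsig[j, i] <- TRUE
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
  }
  list(order = ord, nonsig = nonsig)
}

# Shared-letter matrix of a letter_display, in its own (descending) order.
shared_letter_matrix <- function(ld) {
  lets <- strsplit(ld$entries$letters, "")
  k <- length(lets)
  out <- diag(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- length(intersect(lets[[i]], lets[[j]])) > 0
  }
  out
}

# Region-level table-shaped data.frame from a means matrix (regions x
# variables). Deliberately NOT passed through measurement_table(): several
# tests feed standardized (negative) values to the multivariate stages.
table_from_means <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  data.frame(sample_id = rownames(m), region = rownames(m), species = "sp",
             as.data.frame(m), stringsAsFactors = FALSE)
}
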