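# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive double loops / direct
# formulas, not the code paths under test.

# all-pairs inter-chain residue contact search over an atom tibble
oracle_contacts <- function(atoms, cutoff = 4) {
  atoms <- atoms[!atoms$is_ligand & !(atoms$elesy %in% c("H", "D")), ]
  res <- unique(atoms[, c("chain", "resno")])
  out <- NULL
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (res$chain[i] >= res$chain[j]) next
      ai <- atoms[atoms$chain == res$chain[i] & atoms$resno == res$resno[i], ]
      aj <- atoms[atoms$chain == res$chain[j] & atoms$resno == res$resno[j], ]
      dmin <- Inf
      for (k in seq_len(nrow(ai))) {
        for (l in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[k] - aj$x[l])^2 + (ai$y[k] - aj$y[l])^2 +
                      (ai$z[k] - aj$z[l])^2)
          dmin <- min(dmin, d)
        }
      }
      if (dmin <= cutoff) {
        out <- rbind(out, data.frame(
          chain_a = res$chain[i], pos_a = res$resno[i],
          chain_b = res$chain[j], pos_b = res$resno[j], min_distance = dmin
        ))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(chain_a = character(), pos_a = integer(),
                      chain_b = character(), pos_b = integer(),
                      min_distance = double()))
  }
  out[order(out$chain_a, out$pos_a, out$chain_b, out$pos_b), ]
}

# hand product-limit estimator: events precede censorings at tied times
oracle_km <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  out <- NULL
  for (t in ut) {
    n_i <- sum(time >= t)            # ties: censored at t still at risk
    d_i <- sum(time == t & status == 1)
    s <- s * (1 - d_i / n_i)
    out <- rbind(out, data.frame(time = t, n_risk = n_i, n_event = d_i,
                                 survival = s))
  }
  out
}

# two-group log-rank: sum over event times of (O - E), hypergeometric var
oracle_logrank2 <- function(time, status, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ut <- sort(unique(time[status == 1]))
  OmE <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group == g[1])
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- OmE^2 / V
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# textbook Pearson chi-square
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# column-walking residue map oracle
oracle_residue_map <- function(s, t) {
  sc <- strsplit(s, "")[[1]]; tc <- strsplit(t, "")[[1]]
  sp <- 0; tp <- 0
  out <- NULL
  for (k in seq_along(sc)) {
    if (sc[k] != "-") sp <- sp + 1
    if (tc[k] != "-") tp <- tp + 1
    if (sc[k] != "-" && tc[k] != "-") {
      out <- rbind(out, data.frame(source_pos = sp, target_pos = tp))
    }
  }
  out
}

# a tiny deterministic multi-chain atom tibble for direct geometry tests
toy_model <- function(pdb_lines, chain_map = NULL) {
  read_structure(paste(pdb_lines, collapse = "\n"), chain_map = chain_map)
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = "", elesy = "C", record = "ATOM") {
  sprintf("%-6s%5d %s%-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(elety) >= 4, "", " "),
          elety, alt, resid, chain, resno, x, y, z, occ, 0, elesy)
}

# random survival cohort in the case-table schema
random_cohort <- function(n, seed, rate = 0.02, cens = c(20, 90)) {
  set.seed(seed)
  t_ev <- rexp(n, rate)
  t_c <- runif(n, cens[1], cens[2])
  died <- t_ev <= t_c
  tibble::tibble(
    case_id = paste0("c", seq_len(n)), gene = "TNNT2",
    variant = "R92Q", index_flag = 1L, phenotype = "HCM",
    last_followup_age = ifelse(died, t_ev, t_c),
    cv_death = as.integer(died), scd = as.integer(died),
    hf_death_tx = 0L, stroke_death = 0L, proc_death = 0L,
    n_path_variants = 1L, ref_aa = "R", position = 92L, alt_aa = "Q"
  )
}
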