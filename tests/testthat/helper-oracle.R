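# Brute-force straight-line recomputation of the scoring pipeline in base R,
# kept deliberately free of package internals: plain loops and vectors only.
# Used to cross-check the dplyr pipeline on tiny screens.

oracle_scores <- function(plates, layout, screens, min_replicates = 6,
                          mad_mult = 5) {
  role_at <- function(r, c) layout$role[layout$row == r & layout$col == c]
  strain_at <- function(r, c) layout$strain_id[layout$row == r & layout$col == c]

  # --- per-plate normalization: scale + alternating row/col median polish
  norm <- list()
  for (pid in unique(plates$plate_id)) {
    p <- plates[plates$plate_id == pid, ]
    role <- character(nrow(p)); strain <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
      role[i] <- role_at(p$row[i], p$col[i])
      strain[i] <- strain_at(p$row[i], p$col[i])
    }
    elig <- role == "array" & !is.na(p$size) & p$size > 0
    strain_meds <- function(v, s) {
      out <- numeric(0)
      for (u in unique(s)) out <- c(out, median(v[s == u]))
      out
    }
    rel <- p$size / median(strain_meds(p$size[elig], strain[elig]))
    corr <- rep(1, nrow(p))
    for (iter in 1:25) {
      resid <- rel / corr
      dr <- rep(1, nrow(p))
      for (r in unique(p$row)) {
        sel <- p$row == r & elig
        if (any(sel)) {
          m <- median(resid[sel])
          if (is.finite(m) && m > 0) dr[p$row == r] <- m
        }
      }
      corr <- corr * dr
      resid <- resid / dr
      dc <- rep(1, nrow(p))
      for (cc in unique(p$col)) {
        sel <- p$col == cc & elig
        if (any(sel)) {
          m <- median(resid[sel])
          if (is.finite(m) && m > 0) dc[p$col == cc] <- m
        }
      }
      corr <- corr * dc
      if (max(abs(dr - 1), abs(dc - 1)) < 1e-12) break
    }
    rel <- rel / corr
    rel <- rel / median(strain_meds(rel[elig], strain[elig]))
    # outlier flags: per strain within plate, raw-MAD rule, >= 3 replicates
    out <- rep(FALSE, nrow(p))
    for (s in unique(strain[!is.na(strain)])) {
      sel <- which(!is.na(strain) & strain == s & role == "array" &
                     !is.na(rel))
      if (length(sel) >= 3) {
        med <- median(rel[sel])
        madv <- median(abs(rel[sel] - med))
        out[sel] <- abs(rel[sel] - med) > mad_mult * madv
      }
    }
    norm[[pid]] <- data.frame(p, role = role, strain = strain, rel = rel,
                              outlier = out, stringsAsFactors = FALSE)
  }
  norm <- do.call(rbind, norm)
  usable <- norm$role == "array" & !is.na(norm$rel) & !norm$outlier

  sid2q <- setNames(screens$query_id, screens$screen_id)
  sid2role <- setNames(screens$query_role, screens$screen_id)

  # --- single-mutant fitness from the control cross
  singles <- new.env()
  ctrl <- norm[usable & sid2role[norm$screen_id] == "control_query", ]
  for (s in unique(ctrl$strain)) {
    assign(s, mean(ctrl$rel[ctrl$strain == s]), envir = singles)
  }
  f_of <- function(s) if (exists(s, envir = singles)) get(s, envir = singles)
                      else NA_real_

  # --- double-mutant fitness, pooled colonies, query rescale
  qry <- norm[usable & sid2role[norm$screen_id] == "query" &
                norm$condition == "selection", ]
  qry$query <- unname(sid2q[qry$screen_id])
  recs <- list()
  for (q in unique(qry$query)) {
    for (a in unique(layout$strain_id[layout$role == "array"])) {
      v <- qry$rel[qry$query == q & qry$strain == a]
      recs[[paste(q, a)]] <- data.frame(
        query = q, array = a, n = length(v),
        obs = if (length(v)) mean(v) * f_of(q) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, recs)

  # --- reciprocal merge at the colony level, canonical ordering
  merged <- list()
  done <- character()
  for (i in seq_len(nrow(recs))) {
    q <- recs$query[i]; a <- recs$array[i]
    k <- paste(min(q, a), max(q, a))
    if (k %in% done) next
    done <- c(done, k)
    j <- which(recs$query == a & recs$array == q)
    if (q != a && length(j) == 1) {
      n <- recs$n[i] + recs$n[j]
      obs <- (recs$n[i] * recs$obs[i] + recs$n[j] * recs$obs[j]) / n
    } else {
      n <- recs$n[i]; obs <- recs$obs[i]
    }
    merged[[k]] <- data.frame(query = min(q, a), array = max(q, a),
                              n = n, obs = obs, self = q == a,
                              stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, merged)
  merged$expected <- NA_real_
  merged$score <- NA_real_
  for (i in seq_len(nrow(merged))) {
    merged$expected[i] <- f_of(merged$query[i]) * f_of(merged$array[i])
    merged$score[i] <- merged$obs[i] - merged$expected[i]
  }
  merged$low <- merged$n < min_replicates
  merged[order(merged$query, merged$array), ]
}
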