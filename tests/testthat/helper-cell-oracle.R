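# Independent R transcription of the coupled-unit right-hand side, used to
# cross-check the compiled implementation and as the reference integrator
# for AP morphology.  Written directly from the published model equations;
# state layout matches cell_initial_state().
oracle_cell_derivs <- function(y, i_stim = 0, numf = 3, ggap = 0.5,
                               cm_myo = 0.05, cm_fb = 0.0063) {
  RTF <- 8314 * 306.15 / 96487
  Farad <- 96487
  Vol_i <- 0.005884; Vol_c <- 0.136 * Vol_i; Vol_d <- 0.02 * Vol_i
  Vol_rel <- 0.0000441; Vol_up <- 0.0003969

  V <- y["V"]; Na_c <- y["Na_c"]; K_c <- y["K_c"]; Ca_c <- y["Ca_c"]
  Na_i <- y["Na_i"]; K_i <- y["K_i"]; Ca_i <- y["Ca_i"]; Ca_d <- y["Ca_d"]

  E_Na <- RTF * log(Na_c / Na_i)
  E_K <- RTF * log(K_c / K_i)
  E_Ca <- RTF / 2 * log(Ca_c / Ca_i)

  INa <- 0.0016 * y["m"]^3 * (0.9 * y["h1"] + 0.1 * y["h2"]) * Na_c * V *
    Farad / RTF * (exp((V - E_Na) / RTF) - 1) / (exp(V / RTF) - 1)
  fca <- Ca_d / (Ca_d + 0.025)
  ICaL <- 6.75 * y["d_L"] * (fca * y["f_L1"] + (1 - fca) * y["f_L2"]) * (V - 60)
  It <- 7.5 * y["r"] * y["s"] * (V - E_K)
  Isus <- 2.75 * y["r_sus"] * y["s_sus"] * (V - E_K)
  IKs <- 1 * y["n"] * (V - E_K)
  IKr <- 0.5 * y["p_a"] * (1 / (1 + exp((V + 55) / 24))) * (V - E_K)
  IK1 <- 3 * K_c^0.4457 * (V - E_K) / (1 + exp(1.5 * (V - E_K + 3.6) / RTF))
  IBNa <- 0.060599 * (V - E_Na)
  IBCa <- 0.078681 * (V - E_Ca)
  INaK <- 70.8253 * (K_c / (K_c + 1)) * (Na_i^1.5 / (Na_i^1.5 + 11^1.5)) *
    (V + 150) / (V + 200)
  ICaP <- 4 * Ca_i / (Ca_i + 0.0002)
  INaCa <- 0.0374842 *
    (Na_i^3 * Ca_c * exp(0.45 * V / RTF) -
     Na_c^3 * Ca_i * exp(-0.55 * V / RTF)) /
    (1 + 0.0003 * (Ca_i * Na_c^3 + Ca_c * Na_i^3))

  Vfb <- y["V_fb"]
  Igap <- ggap * (V - Vfb)
  Imyo <- INa + ICaL + It + Isus + IK1 + IKr + IKs + IBNa + IBCa + INaK +
    ICaP + INaCa

  d <- numeric(length(y)); names(d) <- names(y)
  d["V"] <- -(Imyo + i_stim + numf * Igap) / cm_myo

  gate <- function(cur, inf, tau) (inf - cur) / tau
  d["m"] <- gate(y["m"], 1 / (1 + exp(-(V + 27.12) / 8.21)),
                 4.2e-5 * exp(-((V + 25.57) / 28.8)^2) + 2.4e-5)
  hinf <- 1 / (1 + exp((V + 63.6) / 5.3))
  d["h1"] <- gate(y["h1"], hinf, 0.03 / (1 + exp((V + 35.1) / 3.2)) + 3e-4)
  d["h2"] <- gate(y["h2"], hinf, 0.12 / (1 + exp((V + 35.1) / 3.2)) + 3e-3)
  d["d_L"] <- gate(y["d_L"], 1 / (1 + exp(-(V + 9) / 5.8)),
                   0.0027 * exp(-((V + 35) / 30)^2) + 0.002)
  flinf <- 1 / (1 + exp((V + 27.4) / 7.1))
  d["f_L1"] <- gate(y["f_L1"], flinf, 0.161 * exp(-((V + 40) / 14.4)^2) + 0.01)
  d["f_L2"] <- gate(y["f_L2"], flinf, 1.3323 * exp(-((V + 40) / 14.2)^2) + 0.0626)
  d["r"] <- gate(y["r"], 1 / (1 + exp(-(V - 1) / 11)),
                 0.0035 * exp(-(V / 30)^2) + 0.0015)
  d["s"] <- gate(y["s"], 1 / (1 + exp((V + 40.5) / 11.5)),
                 0.4812 * exp(-((V + 52.45) / 14.97)^2) + 0.01414)
  d["r_sus"] <- gate(y["r_sus"], 1 / (1 + exp(-(V + 4.3) / 8)),
                     0.009 / (1 + exp((V + 5) / 12)) + 5e-4)
  d["s_sus"] <- gate(y["s_sus"], 0.4 / (1 + exp((V + 20) / 10)) + 0.6,
                     0.047 / (1 + exp((V + 60) / 10)) + 0.3)
  d["n"] <- gate(y["n"], 1 / (1 + exp(-(V - 19.9) / 12.7)),
                 0.7 + 0.4 * exp(-((V - 20) / 20)^2))
  d["p_a"] <- gate(y["p_a"], 1 / (1 + exp(-(V + 15) / 6)),
                   0.03118 + 0.21718 * exp(-((V + 20.1376) / 22.1996)^2))

  Iup <- 2800 * (Ca_i / 3e-4 - 0.16 * y["Ca_up"] / 0.5) /
    ((Ca_i + 3e-4) / 3e-4 + 0.4 * (y["Ca_up"] + 0.5) / 0.5)
  Itr <- (y["Ca_up"] - y["Ca_rel"]) * 2 * Farad * Vol_rel / 0.01
  Irel <- 2e5 * (y["F2"] / (y["F2"] + 0.25))^2 * (y["Ca_rel"] - Ca_i)
  acti <- (Ca_i / (Ca_i + 3e-4))^4
  actd <- (Ca_d / (Ca_d + 3e-3))^4
  ract <- 203.8 * (acti + actd)
  rinact <- 33.96 + 339.6 * acti
  d["F1"] <- 0.815 * (1 - y["F1"] - y["F2"]) - ract * y["F1"]
  d["F2"] <- ract * y["F1"] - rinact * y["F2"]
  dOCalse <- 480 * y["Ca_rel"] * (1 - y["O_Calse"]) - 400 * y["O_Calse"]
  dOC <- 2e5 * Ca_i * (1 - y["O_C"]) - 476 * y["O_C"]
  dOTC <- 78400 * Ca_i * (1 - y["O_TC"]) - 392 * y["O_TC"]
  dOTMgC <- 2e5 * Ca_i * (1 - y["O_TMgC"] - y["O_TMgMg"]) - 6.6 * y["O_TMgC"]
  dOTMgMg <- 2000 * 2.5 * (1 - y["O_TMgC"] - y["O_TMgMg"]) - 666 * y["O_TMgMg"]
  d["O_Calse"] <- dOCalse; d["O_C"] <- dOC; d["O_TC"] <- dOTC
  d["O_TMgC"] <- dOTMgC; d["O_TMgMg"] <- dOTMgMg
  d["Ca_up"] <- (Iup - Itr) / (2 * Vol_up * Farad)
  d["Ca_rel"] <- (Itr - Irel) / (2 * Vol_rel * Farad) - 31 * dOCalse
  Idi <- (Ca_d - Ca_i) * 2 * Farad * Vol_d / 0.01
  d["Ca_d"] <- -(ICaL + Idi) / (2 * Vol_d * Farad)
  d["Ca_i"] <- -(-Idi + IBCa + ICaP - 2 * INaCa + Iup - Irel) /
    (2 * Vol_i * Farad) - (0.045 * dOC + 0.08 * dOTC + 0.16 * dOTMgC)
  naf <- INa + IBNa + 3 * INaK + 3 * INaCa - 1.68
  kf <- It + Isus + IK1 + IKs + IKr - 2 * INaK
  d["Na_c"] <- (130 - Na_c) / 14.3 + naf / (Vol_c * Farad)
  d["K_c"] <- (5.4 - K_c) / 10 + kf / (Vol_c * Farad)
  d["Ca_c"] <- (1.8 - Ca_c) / 24.7 +
    (ICaL + IBCa + ICaP - 2 * INaCa) / (2 * Vol_c * Farad)
  d["Na_i"] <- -naf / (Vol_i * Farad)
  d["K_i"] <- -kf / (Vol_i * Farad)

  # active fibroblast
  EKf <- RTF * log(5.4 / 129.4349)
  ENaf <- RTF * log(130 / 8.5547)
  IKv <- 0.25 * 6.3 * y["r_fb"] * y["s_fb"] * (Vfb - EKf)
  IK1f <- 0.4822 * 6.3 * (Vfb - EKf) / (1 + exp(0.0896 * (Vfb - EKf)))
  INaKf <- 2.002 * 6.3 * (5.4 / 6.4) * (8.5547^1.5 / (8.5547^1.5 + 11^1.5)) *
    (Vfb + 150) / (Vfb + 200)
  IbNaf <- 0.0890 * (Vfb - ENaf)
  d["V_fb"] <- -(IKv + IK1f + INaKf + IbNaf - Igap) / cm_fb
  d["r_fb"] <- gate(y["r_fb"], 1 / (1 + exp(-(Vfb + 20) / 11)),
                    (20.3 + 138 * exp(-((Vfb + 20) / 25.9)^2)) / 1000)
  d["s_fb"] <- gate(y["s_fb"], 1 / (1 + exp((Vfb + 23) / 7)),
                    (1574 + 5268 * exp(-((Vfb + 23) / 22.7)^2)) / 1000)
  d
}

# Classical RK4 reference integration of the oracle RHS.
oracle_cell_rk4 <- function(y, t_end, dt = 2e-5, i_stim_fun = function(t) 0,
                            ...) {
  n <- round(t_end / dt)
  out_t <- numeric(n %/% 10 + 1)
  out_v <- numeric(n %/% 10 + 1)
  out_t[1] <- 0; out_v[1] <- y["V"]
  rec <- 1
  for (s in seq_len(n)) {
    t <- (s - 1) * dt
    k1 <- oracle_cell_derivs(y, i_stim_fun(t), ...)
    k2 <- oracle_cell_derivs(y + dt / 2 * k1, i_stim_fun(t + dt / 2), ...)
    k3 <- oracle_cell_derivs(y + dt / 2 * k2, i_stim_fun(t + dt / 2), ...)
    k4 <- oracle_cell_derivs(y + dt * k3, i_stim_fun(t + dt), ...)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% 10 == 0) {
      rec <- rec + 1
      out_t[rec] <- s * dt
      out_v[rec] <- y["V"]
    }
  }
  list(time = out_t, V = out_v, state = y)
}

ap_metrics <- function(time, v, stim_end) {
  rest <- v[1]
  peak_i <- which.max(v)
  peak <- v[peak_i]
  v90 <- peak - 0.9 * (peak - rest)
  below <- which(v[(peak_i + 1):length(v)] < v90)
  list(rest = rest, peak = peak, amplitude = peak - rest,
       apd90_ms = if (length(below)) (time[peak_i + below[1]] - stim_end) * 1000 else NA)
}
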