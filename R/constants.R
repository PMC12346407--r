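# Physical and method constants.

# Universal gas constant, J mol^-1 K^-1.
GAS_CONSTANT <- 8.314

# Doyle approximation constants of the base-10 isoconversional regression
# log10(beta) = log10(A*Ea/R) - 2.315 - 0.4567 * Ea/(R*T).
DOYLE_C1 <- 2.315
DOYLE_C2 <- 0.4567

# Fixed analysis windows (nm) for derivative features and areas.
WINDOW_1 <- c(420, 450)
WINDOW_2 <- c(455, 480)

# Canonical design-table column names.
DESIGN_COLS <- c("conc_mg_g", "time_days", "To_C", "Ea_kJ_mol", "PV_meqO2_kg", "TBA")
RESPONSE_COLS <- DESIGN_COLS[3:6]
RESPONSE_ALIASES <- c(Y1 = "To_C", Y2 = "Ea_kJ_mol", Y3 = "PV_meqO2_kg", Y4 = "TBA",
                      To = "To_C", Ea = "Ea_kJ_mol", PV = "PV_meqO2_kg", TBA = "TBA")
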