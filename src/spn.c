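/* Compiled right-hand side of the segment polarity network ODEs.
 *
 * The model state is laid out cell-major, 33 species per cell:
 *   0 en, 1 wg, 2 ptc, 3 ci, 4 hh,          (mRNA)
 *   5 EN, 6 IWG, 7 CI, 8 CN,                (cytosolic proteins)
 *   9..14 EWG_j, 15..20 PTC_j, 21..26 HH_j, 27..32 PH_j  (sides 1..6)
 *
 * Parameters arrive in the canonical 53-slot order of spn_parameters().
 * Topology arrives as a (cell, side) -> neighbor-cell map; -1 marks a
 * fixed-concentration boundary (single-cell variant), whose pool values
 * are supplied separately, indexed by the neighbor's own side.
 *
 * Model data are stored in static buffers set by C_spn_set_model(); the
 * integrator entry point spn_derivs() has the deSolve compiled-function
 * signature.  Not re-entrant: one model is active at a time.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NSP 33                  /* species per cell */
#define NPAR 53

/* parameter slots (canonical order) */
enum {
  iH_en = 0, iH_EN, iH_wg, iH_IWG, iH_EWG, iH_ptc, iH_PTC, iH_ci,
  iH_CI, iH_CN, iH_hh, iH_HH, iH_PH,         /* 0..12 half-lives */
  iKAPPA0 = 13,                               /* 11 (kappa, nu) pairs */
  iALPHA = 35, iBETA, iC_CI, iK_BIND, iR_EXO, iR_ENDO,
  iT_EN = 41, iT_IWG, iT_PTC, iT_CI, iT_HH,
  iPTC0 = 46, iHH0, iB, iVMAX, iRM_WG, iRM_PTC, iRM_HH
};

/* regulatory arrows, order of the (kappa, nu) pairs */
enum { aWGen = 0, aCNen, aCIwg, aCNwg, aWGwg, aCIptc, aCNptc,
       aENci, aPTCCI, aENhh, aCNhh };

static double P[NPAR];
static double DEC[13];          /* ln2 / H */
static double KNU[11];          /* kappa^nu (never guarded) */
static int   *NBR = NULL;       /* 6 * n_cells */
static int    NCELL = 0;
static int    GUARD = 1;
static double EPS = 1e-80;
static double BEWG[6], BPTC[6], BHH[6];   /* single-cell boundary pools */

static R_INLINE double gpow(double b, double e)
{
  if (GUARD && b < EPS) b = EPS;
  return pow(b, e);
}

static R_INLINE double hill_act(double x, double knu, double nu)
{
  double xp = gpow(x, nu);
  return xp / (knu + xp);
}

static R_INLINE double hill_rep(double x, double knu, double nu)
{
  double s = 1.0 - hill_act(x, knu, nu);
  if (GUARD && s < EPS) s = EPS;
  return s;
}

/* inducer-repressor transcription law (without the V factor) */
static R_INLINE double txn(double I, double R,
                           double k1nu, double h1, double k2nu, double h2)
{
  double num = I * hill_rep(R, k2nu, h2);
  double nh = gpow(num, h1);
  return nh / (k1nu + nh);
}

static void spn_core(const double *y, double *ydot)
{
  const double alpha = P[iALPHA], beta = P[iBETA], cci = P[iC_CI],
    kb = P[iK_BIND], rexo = P[iR_EXO], rendo = P[iR_ENDO],
    tEN = P[iT_EN], tIWG = P[iT_IWG], tPTC = P[iT_PTC],
    tCI = P[iT_CI], tHH = P[iT_HH],
    ptc0 = P[iPTC0], hh0 = P[iHH0], B = P[iB], V = P[iVMAX],
    rmW = P[iRM_WG], rmP = P[iRM_PTC], rmH = P[iRM_HH];

  for (int c = 0; c < NCELL; c++) {
    const double *yc = y + NSP * c;
    double *dc = ydot + NSP * c;
    const double en = yc[0], wg = yc[1], ptc = yc[2], ci = yc[3],
      hh = yc[4], EN = yc[5], IWG = yc[6], CI = yc[7], CN = yc[8];
    const double *EWG = yc + 9, *PTC = yc + 15, *HH = yc + 21,
      *PH = yc + 27;

    double ewgT = 0.0, sumEWG = 0.0, ptcT = 0.0;
    double HHn[6], PTCn[6];
    for (int j = 0; j < 6; j++) {
      const int nb = NBR[6 * c + j];
      const int jop = (j + 3) % 6;
      if (nb >= 0) {
        ewgT   += y[NSP * nb + 9 + jop];
        HHn[j]  = y[NSP * nb + 21 + jop];
        PTCn[j] = y[NSP * nb + 15 + jop];
      } else {
        ewgT   += BEWG[jop];
        HHn[j]  = BHH[jop];
        PTCn[j] = BPTC[jop];
      }
      sumEWG += EWG[j];
      ptcT += PTC[j];
    }

    /* mRNAs */
    dc[0] = V * txn(ewgT, CN, KNU[aWGen], P[iKAPPA0 + 2*aWGen + 1],
                    KNU[aCNen], P[iKAPPA0 + 2*aCNen + 1]) - DEC[iH_en] * en;
    {
      double aci = alpha * hill_act(CI, KNU[aCIwg], P[iKAPPA0 + 2*aCIwg + 1]);
      double pcn = hill_rep(CN, KNU[aCNwg], P[iKAPPA0 + 2*aCNwg + 1]);
      double awg = beta * hill_act(IWG, KNU[aWGwg], P[iKAPPA0 + 2*aWGwg + 1]);
      double num = aci * pcn + awg;
      dc[1] = V * num / (1.0 + num) - DEC[iH_wg] * wg;
    }
    dc[2] = V * txn(CI, CN, KNU[aCIptc], P[iKAPPA0 + 2*aCIptc + 1],
                    KNU[aCNptc], P[iKAPPA0 + 2*aCNptc + 1]) - DEC[iH_ptc] * ptc;
    dc[3] = V * B * hill_rep(EN, KNU[aENci], P[iKAPPA0 + 2*aENci + 1])
      - DEC[iH_ci] * ci;
    dc[4] = V * txn(EN, CN, KNU[aENhh], P[iKAPPA0 + 2*aENhh + 1],
                    KNU[aCNhh], P[iKAPPA0 + 2*aCNhh + 1]) - DEC[iH_hh] * hh;

    /* cytosolic proteins */
    dc[5] = tEN * en - DEC[iH_EN] * EN;
    dc[6] = tIWG * wg + rendo * sumEWG - rexo * IWG - DEC[iH_IWG] * IWG;
    {
      double cleave = cci * CI * hill_act(ptcT, KNU[aPTCCI],
                                          P[iKAPPA0 + 2*aPTCCI + 1]);
      dc[7] = tCI * ci - cleave - DEC[iH_CI] * CI;
      dc[8] = cleave - DEC[iH_CN] * CN;
    }

    /* membrane pools */
    for (int j = 0; j < 6; j++) {
      const int jp = (j + 1) % 6, jm = (j + 5) % 6;
      const double bindPH = kb * hh0 * PTC[j] * HHn[j];
      dc[9 + j] = (rexo / 6.0) * IWG - rendo * EWG[j]
        + rmW * (EWG[jp] + EWG[jm] - 2.0 * EWG[j]) - DEC[iH_EWG] * EWG[j];
      dc[15 + j] = (tPTC / 6.0) * ptc
        + rmP * (PTC[jp] + PTC[jm] - 2.0 * PTC[j])
        - bindPH - DEC[iH_PTC] * PTC[j];
      dc[21 + j] = (tHH / 6.0) * hh
        + rmH * (HH[jp] + HH[jm] - 2.0 * HH[j])
        - kb * ptc0 * PTCn[j] * HH[j] - DEC[iH_HH] * HH[j];
      dc[27 + j] = bindPH - DEC[iH_PH] * PH[j];
    }
  }
}

/* ---- deSolve compiled-function interface ---- */

void spn_init(void (*odeparms)(int *, double *))
{
  /* model data are installed by C_spn_set_model(); nothing to do here */
}

void spn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  spn_core(y, ydot);
}

/* ---- .Call interface ---- */

SEXP C_spn_set_model(SEXP pars, SEXP nbr, SEXP guard_on, SEXP eps,
                     SEXP boundary)
{
  if (LENGTH(pars) != NPAR)
    error("expected %d parameters, got %d", NPAR, LENGTH(pars));
  if (LENGTH(nbr) % 6 != 0 || LENGTH(nbr) == 0)
    error("neighbor map length must be a positive multiple of 6");
  memcpy(P, REAL(pars), NPAR * sizeof(double));
  for (int i = 0; i < 13; i++) DEC[i] = M_LN2 / P[i];
  for (int k = 0; k < 11; k++)
    KNU[k] = pow(P[iKAPPA0 + 2 * k], P[iKAPPA0 + 2 * k + 1]);

  int n = LENGTH(nbr) / 6;
  if (NBR != NULL) { R_Free(NBR); NBR = NULL; }
  NBR = R_Calloc((size_t) LENGTH(nbr), int);
  memcpy(NBR, INTEGER(nbr), LENGTH(nbr) * sizeof(int));
  NCELL = n;

  GUARD = asLogical(guard_on) == TRUE;
  EPS = asReal(eps);

  if (LENGTH(boundary) == 18) {
    const double *b = REAL(boundary);
    for (int j = 0; j < 6; j++) {
      BEWG[j] = b[j]; BPTC[j] = b[6 + j]; BHH[j] = b[12 + j];
    }
  } else {
    for (int j = 0; j < 6; j++) BEWG[j] = BPTC[j] = BHH[j] = 0.0;
  }
  return ScalarInteger(NCELL);
}

SEXP C_spn_rhs(SEXP state)
{
  if (LENGTH(state) != NSP * NCELL)
    error("state length %d does not match model (%d species)",
          LENGTH(state), NSP * NCELL);
  SEXP out = PROTECT(allocVector(REALSXP, LENGTH(state)));
  spn_core(REAL(state), REAL(out));
  UNPROTECT(1);
  return out;
}

/* ---- registration ---- */

static const R_CallMethodDef call_entries[] = {
  {"C_spn_set_model", (DL_FUNC) &C_spn_set_model, 5},
  {"C_spn_rhs",       (DL_FUNC) &C_spn_rhs,       1},
  {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
  {"spn_derivs", (DL_FUNC) &spn_derivs, 6},
  {"spn_init",   (DL_FUNC) &spn_init,   1},
  {NULL, NULL, 0}
};

void R_init_spnsim(DllInfo *dll)
{
  R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
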