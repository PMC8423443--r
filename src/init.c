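#include <R.h>
#include <Rinternals.h>
#include <stdlib.h>
#include <R_ext/Rdynload.h>

/* .Call entries generated by Rcpp attributes (RcppExports.cpp) */
extern SEXP _toxwar_sim_competition_cpp(SEXP, SEXP, SEXP, SEXP);
extern SEXP _toxwar_self_cross_final_cpp(SEXP, SEXP);
extern SEXP _toxwar_cross_final_cpp(SEXP, SEXP, SEXP);

/* compiled ODE right-hand side for deSolve */
extern void toxwar_initmod(void (*odeparms)(int *, double *));
extern void toxwar_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"_toxwar_sim_competition_cpp",  (DL_FUNC) &_toxwar_sim_competition_cpp,  4},
  {"_toxwar_self_cross_final_cpp", (DL_FUNC) &_toxwar_self_cross_final_cpp, 2},
  {"_toxwar_cross_final_cpp",      (DL_FUNC) &_toxwar_cross_final_cpp,      3},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"toxwar_initmod", (DL_FUNC) &toxwar_initmod, 1},
  {"toxwar_derivs",  (DL_FUNC) &toxwar_derivs,  6},
  {NULL, NULL, 0}
};

void R_init_toxwar(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
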