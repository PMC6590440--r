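>Ancestor IR
+psbA +trnQ +psbK +trnF +rps4 +ycf2 +clpP +REP +ndhF +ycf1 +chlN +chlL
>Skra DR
+psbA +trnQ +psbK +trnF -REP -clpP -ycf2 -rps4 +ndhF +ycf1 +chlN +chlL
>Stam DR
+psbA +trnQ +psbK +trnF -REP -clpP -ycf2 -rps4 -ycf1 -ndhF +chlN +chlL
>Smoe IR
+psbA +trnQ +psbK +trnF -ndhF +rps4 +ycf2 +clpP +REP +ycf1 +chlN +chlL
>Slep IR
+psbA +trnQ +psbK +trnF -ycf1 -ndhF +rps4 +ycf2 +clpP +REP +chlN +chlL
>Iso IR
+psbA +trnQ +psbK +trnF +rps4 +clpP +REP -ycf2 +ndhF +ycf1 +chlN +chlL
>Sunc IR
+psbA +ndhF -trnF -psbK -trnQ -psbK -trnQ +REP +ycf1 +ycf2 +clpP +rps4 +chlN +chlL
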