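>RHOD
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGKPRYRHNTWEKRRADILRYCHHRWEKMPVDFLRTCHKQSAGIPVYFLNRRSKCFS------------------------
>RND1
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGLPRYFENSWEKDSADILEYCHQSWEGMPVDFLRTCHKQSAGIPVYFLNSSQNSSKSLMSRGRSAGSERSHHGNQ-----
>RAC1
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGQPRYFHNTWEKESADILRYCHNTWEGMPVDFLRTCHKQSAGIPVYFLNAPNVPIILVGNKKDLESTRAVS---------
>RHOA
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGTPRYFHNTWEKDSADILRYCHSEWEGMPVDFLRTCHKQSAGIPVYFLNGSQNGCINCCKVLSA----------------
>CDC42
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGKPRYFHNTWEKRSADILRYCHKRWEGMPVDFLRTCHKQSAGIPVYFLNKKSRRCVL-----------------------
>RIF
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGSPRYFHNTWEKESADILRYCHDNWEGMPVDFLRTCHKQSAGIPVYFLNQQSTGEKSSNCCAIMNGQGVD----------
>RND3
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGAPRYFENTWEKESADILRYCHSDWEGMPVDFLRTCHKQSAGIPVYFLNSSHTDLHLASQSNGSKSTDRSAQGSGSEVHS
>RHBT1
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGRPRYFHNTWEKKSADILRYCHRKWEGMPVDFLRTCHKQSAGIPVYFLNKRSGCF-------------------------
>RHBT2
NQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGIPRYFHNTWEKMSADILRYCHNQWEGMPVDFLRTCHKQSAGIPVYFLNTCEKMSADIPRYFHNQWEGMSVDILRTCHKQWAGMPVDFLNTCEKQSAGKPRYFHNTWEKRSADILRYCHKHWEGMPVDFLRTCHKQSAGIPVYFLNRKSAC--------------------------
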