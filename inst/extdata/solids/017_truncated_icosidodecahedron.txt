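# 17|truncated icosidodecahedron|Archimedean
-2.86727774836 -1.52687183554 -1.97625520722
-2.42482836925 -1.04848134712 -2.73479399168
-3.32730882724 -0.679730390945 -1.71031765946
-2.88485944814 -0.201339902524 -2.46885644391
-2.75732639808 -2.26599682097 -1.31172156888
-2.13697199712 -2.98353568091 -0.995022339833
-3.10740612669 -2.1579803618 -0.381250382781
-2.48705172573 -2.87551922174 -0.0645511537298
-0.084821328761 -2.15297040053 -3.13300618083
0.0251300215158 -2.89209538596 -2.46847254249
0.901351477295 -1.98844073114 -3.1131773007
1.01130282757 -2.72756571657 -2.44864366236
-1.59897888528 -1.01355426239 -3.29760188836
-0.705175729726 -1.43543154059 -3.44970540988
-1.23316048019 -0.131485733063 -3.59447223728
-0.339357324634 -0.553363011263 -3.74657575881
-1.24316884157 -3.40541295911 -1.14712586136
-0.417319357592 -3.37048587438 -1.70993375804
-0.699445414618 -3.71927377814 -0.368758196777
0.126404069357 -3.68434669341 -0.931566093463
-3.67738855585 -0.571713931779 -0.779846473358
-3.56743720557 -1.31083891721 -0.115312835018
-3.8013800764 0.081450858917 -0.0328512531413
-3.69142872612 -0.657674126513 0.631682385199
-2.49357532955 2.28271978993 -1.74053910298
-2.84365505816 2.3907362491 -0.810067916873
-1.79171736613 2.97081166536 -1.55635177944
-2.14179709473 3.07882812452 -0.625880593341
-2.51904104305 0.680728626802 -2.76572679283
-1.69319155907 0.715655711532 -3.32853468952
-2.369583809 1.62955499924 -2.48753432319
-1.54373432503 1.66448208397 -3.05034221988
-3.65192284236 1.03027723135 0.2453412165
-3.28610443727 1.91234576068 -0.0515291324222
-3.39251425804 1.23997861836 1.18806732448
-3.02669585295 2.12204714768 0.89119697556
-2.26794231389 -1.47937241848 2.66947538681
-1.80791123501 -2.32651386308 2.40353783905
-1.49813067889 -1.24808490598 3.26436708551
-1.0380996 -2.09522635058 2.99842953774
-3.43202014181 -0.447972739508 1.57440849318
-3.28256290776 0.500853632927 1.85260096282
-2.88829671486 -0.761833558542 2.35277615776
-2.73883948082 0.186992813893 2.6309686274
-1.94332829878 -3.18938004078 0.71381651085
-1.04952514322 -3.61125731898 0.561712989326
-1.68391971446 -2.97967865377 1.65654261883
-0.790116558906 -3.40155593197 1.50443909731
-1.34867344485 -0.29925853355 3.54255955515
-1.96902784581 0.418280326389 3.2258603261
-0.646815481422 0.388833341876 3.72674687868
-1.26716988239 1.10637220181 3.41004764963
-0.14429644445 -2.51710362878 2.84632601622
-0.0203049239011 -3.17026841948 2.099330796
0.841876361606 -2.35257395939 2.86615489635
0.965867882155 -3.00573875009 2.11915967613
0.339357324634 0.553363011263 3.74657575881
1.23316048019 0.131485733063 3.59447223728
0.705175729726 1.43543154059 3.44970540988
1.59897888528 1.01355426239 3.29760188836
1.54373432503 -1.66448208397 3.05034221988
1.69319155907 -0.715655711532 3.32853468952
2.369583809 -1.62955499924 2.48753432319
2.51904104305 -0.680728626802 2.76572679283
1.26716988239 -1.10637220181 -3.41004764963
0.646815481422 -0.388833341876 -3.72674687868
1.96902784581 -0.418280326389 -3.2258603261
1.34867344485 0.29925853355 -3.54255955515
1.55502625452 -3.0414265356 -1.67027599778
1.11257687541 -3.51981702403 -0.911737213334
2.32483788953 -2.81013902311 -1.07538429909
1.88238851042 -3.28852951153 -0.316845514641
3.02669585295 -2.12204714768 -0.89119697556
3.39251425804 -1.23997861836 -1.18806732448
3.28610443727 -1.91234576068 0.0515291324222
3.65192284236 -1.03027723135 -0.2453412165
2.73883948082 -0.186992813893 -2.6309686274
3.28256290776 -0.500853632927 -1.85260096282
2.88829671486 0.761833558542 -2.35277615776
3.43202014181 0.447972739508 -1.57440849318
-0.965867882155 3.00573875009 -2.11915967613
-0.841876361606 2.35257395939 -2.86615489635
0.0203049239011 3.17026841948 -2.099330796
0.14429644445 2.51710362878 -2.84632601622
-1.88238851042 3.28852951153 0.316845514641
-2.32483788953 2.81013902311 1.07538429909
-1.11257687541 3.51981702403 0.911737213334
-1.55502625452 3.0414265356 1.67027599778
-0.126404069357 3.68434669341 0.931566093463
0.699445414618 3.71927377814 0.368758196777
0.417319357592 3.37048587438 1.70993375804
1.24316884157 3.40541295911 1.14712586136
0.790116558906 3.40155593197 -1.50443909731
1.04952514322 3.61125731898 -0.561712989326
1.68391971446 2.97967865377 -1.65654261883
1.94332829878 3.18938004078 -0.71381651085
1.49813067889 1.24808490598 -3.26436708551
2.26794231389 1.47937241848 -2.66947538681
1.0380996 2.09522635058 -2.99842953774
1.80791123501 2.32651386308 -2.40353783905
-0.901351477295 1.98844073114 3.1131773007
0.084821328761 2.15297040053 3.13300618083
-1.01130282757 2.72756571657 2.44864366236
-0.0251300215158 2.89209538596 2.46847254249
1.79171736613 -2.97081166536 1.55635177944
2.49357532955 -2.28271978993 1.74053910298
2.14179709473 -3.07882812452 0.625880593341
2.84365505816 -2.3907362491 0.810067916873
2.42482836925 1.04848134712 2.73479399168
2.88485944814 0.201339902524 2.46885644391
2.86727774836 1.52687183554 1.97625520722
3.32730882724 0.679730390945 1.71031765946
2.13697199712 2.98353568091 0.995022339833
2.48705172573 2.87551922174 0.0645511537298
2.75732639808 2.26599682097 1.31172156888
3.10740612669 2.1579803618 0.381250382781
3.8013800764 -0.081450858917 0.0328512531413
3.69142872612 0.657674126513 -0.631682385199
3.67738855585 0.571713931779 0.779846473358
3.56743720557 1.31083891721 0.115312835018
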